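# from	to (near-phonetic confusion table, synthetic)
ml	mil
benadryl	bena drill
gabapentin	gaba pentin
tylenol	tie lenol
keppra	kepra
zyrtec	zir tech
claritin	clare it in
miralax	mira lacks
albuterol	al beuterol
melatonin	mella tonin
baclofen	back low fin
prednisone	pred nizone
amoxicillin	a moxie cillin
singulair	singular
zofran	zo fran
ativan	atta van
trileptal	try leptal
clonidine	klonodine
omeprazole	oh mep razole
runny nose	running nose
fever	feever
cough	coff
seizure	seesure
wheezing	weezing
vomiting	vomitting
mg	em gee
congestion	congest chin
diarrhea	dia rea
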