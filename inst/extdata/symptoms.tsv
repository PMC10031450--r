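# term	canonical	concept_id (SNOMED CT-style fixture subset; illustrative ids)
fever	Fever	SCT:386661006
runny nose	Rhinorrhea	SCT:64531003
rhinorrhea	Rhinorrhea	SCT:64531003
cough	Cough	SCT:49727002
coughing	Cough	SCT:49727002
congestion	Nasal congestion	SCT:68235000
stuffy nose	Nasal congestion	SCT:68235000
vomiting	Vomiting	SCT:422400008
throwing up	Vomiting	SCT:422400008
nausea	Nausea	SCT:422587007
diarrhea	Diarrhea	SCT:62315008
constipation	Constipation	SCT:14760008
rash	Rash	SCT:271807003
hives	Urticaria	SCT:126485001
itching	Pruritus	SCT:418290006
headache	Headache	SCT:25064002
migraine	Migraine	SCT:37796009
seizure	Seizure	SCT:91175000
seizures	Seizure	SCT:91175000
tremor	Tremor	SCT:26079004
muscle spasm	Muscle spasm	SCT:45352006
spasm	Muscle spasm	SCT:45352006
pain	Pain	SCT:22253000
stomach ache	Abdominal pain	SCT:21522001
abdominal pain	Abdominal pain	SCT:21522001
sore throat	Sore throat	SCT:162397003
earache	Earache	SCT:16001004
ear pain	Earache	SCT:16001004
wheezing	Wheezing	SCT:56018004
shortness of breath	Dyspnea	SCT:267036007
fatigue	Fatigue	SCT:84229001
tired	Fatigue	SCT:84229001
drowsiness	Drowsiness	SCT:271782001
dizziness	Dizziness	SCT:404640003
insomnia	Insomnia	SCT:193462001
sleepiness	Hypersomnia	SCT:77692006
irritability	Irritability	SCT:55929007
anxiety	Anxiety	SCT:48694002
happiness	Happiness	SCT:112080002
sadness	Sadness	SCT:307077003
mood swings	Mood swings	SCT:18963009
crying	Crying	SCT:271951008
fussiness	Irritability	SCT:55929007
restlessness	Restlessness	SCT:162239002
swelling	Swelling	SCT:65124004
bruising	Bruising	SCT:297950001
bleeding	Bleeding	SCT:131148009
nosebleed	Epistaxis	SCT:12441001
sneezing	Sneezing	SCT:76067001
chills	Chills	SCT:43724002
sweating	Sweating	SCT:161868008
night sweats	Night sweats	SCT:42984000
loss of appetite	Anorexia	SCT:79890006
dehydration	Dehydration	SCT:34095006
drooling	Drooling	SCT:62718007
reflux	Gastroesophageal reflux	SCT:16331000
spit up	Regurgitation	SCT:10743008
gagging	Gagging	SCT:276464002
choking	Choking	SCT:404642006
apnea	Apnea	SCT:1023001
low oxygen	Hypoxemia	SCT:389087006
fast heart rate	Tachycardia	SCT:3424008
high blood sugar	Hyperglycemia	SCT:80394007
low blood sugar	Hypoglycemia	SCT:302866003
weight loss	Weight loss	SCT:89362005
jaundice	Jaundice	SCT:18165001
pale	Pallor	SCT:398979000
lethargy	Lethargy	SCT:214264003
confusion	Confusion	SCT:40917007
agitation	Agitation	SCT:24199005
aggression	Aggressive behavior	SCT:61372001
hallucination	Hallucination	SCT:7011001
numbness	Numbness	SCT:44077006
tingling	Paresthesia	SCT:62507009
weakness	Weakness	SCT:13791008
stiffness	Stiffness	SCT:271587009
limp	Limp	SCT:301822002
blister	Blister	SCT:408462000
infection	Infection	SCT:40733004
redness	Erythema	SCT:70819003
itchy eyes	Eye pruritus	SCT:401141003
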