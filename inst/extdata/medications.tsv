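# term	canonical	concept_id (RxNorm-style fixture subset; illustrative ids)
benadryl	Diphenhydramine	RX:203457
diphenhydramine	Diphenhydramine	RX:3498
gabapentin	Gabapentin	RX:25480
neurontin	Gabapentin	RX:196502
tylenol	Acetaminophen	RX:202433
acetaminophen	Acetaminophen	RX:161
ibuprofen	Ibuprofen	RX:5640
advil	Ibuprofen	RX:153010
motrin	Ibuprofen	RX:202488
allegra	Fexofenadine	RX:1116566
fexofenadine	Fexofenadine	RX:87636
zyrtec	Cetirizine	RX:58930
cetirizine	Cetirizine	RX:20610
claritin	Loratadine	RX:203110
loratadine	Loratadine	RX:28889
water	Water	RX:11295
water irrigation solution	Water Irrigation Solution	RX:1164874
albuterol	Albuterol	RX:435
ventolin	Albuterol	RX:202936
proair	Albuterol	RX:745678
keppra	Levetiracetam	RX:261547
levetiracetam	Levetiracetam	RX:114477
depakote	Valproate	RX:202068
valproate	Valproate	RX:40254
valproic acid	Valproate	RX:11118
baclofen	Baclofen	RX:1292
diazepam	Diazepam	RX:3322
valium	Diazepam	RX:202472
clonidine	Clonidine	RX:2599
melatonin	Melatonin	RX:6916
omeprazole	Omeprazole	RX:7646
prilosec	Omeprazole	RX:203345
ranitidine	Ranitidine	RX:9143
zantac	Ranitidine	RX:196504
miralax	Polyethylene Glycol 3350	RX:218566
polyethylene glycol	Polyethylene Glycol 3350	RX:8516
lamotrigine	Lamotrigine	RX:28439
lamictal	Lamotrigine	RX:151591
oxcarbazepine	Oxcarbazepine	RX:32624
trileptal	Oxcarbazepine	RX:260844
topiramate	Topiramate	RX:38404
topamax	Topiramate	RX:151226
risperidone	Risperidone	RX:35636
risperdal	Risperidone	RX:203058
amoxicillin	Amoxicillin	RX:723
augmentin	Amoxicillin-Clavulanate	RX:151392
azithromycin	Azithromycin	RX:18631
zithromax	Azithromycin	RX:196473
prednisone	Prednisone	RX:8640
prednisolone	Prednisolone	RX:8638
fluticasone	Fluticasone	RX:41126
flovent	Fluticasone	RX:216652
singulair	Montelukast	RX:219246
montelukast	Montelukast	RX:88249
cefdinir	Cefdinir	RX:25037
clonazepam	Clonazepam	RX:2598
klonopin	Clonazepam	RX:202585
phenobarbital	Phenobarbital	RX:8134
oxybutynin	Oxybutynin	RX:32675
ditropan	Oxybutynin	RX:203861
glycopyrrolate	Glycopyrrolate	RX:4955
robinul	Glycopyrrolate	RX:219096
lansoprazole	Lansoprazole	RX:17128
prevacid	Lansoprazole	RX:83156
famotidine	Famotidine	RX:4278
pepcid	Famotidine	RX:196458
ondansetron	Ondansetron	RX:26225
zofran	Ondansetron	RX:196511
hydroxyzine	Hydroxyzine	RX:5553
atarax	Hydroxyzine	RX:202416
lorazepam	Lorazepam	RX:6470
ativan	Lorazepam	RX:202479
levocarnitine	Levocarnitine	RX:6339
carnitor	Levocarnitine	RX:216834
vitamin d	Cholecalciferol	RX:2418
cholecalciferol	Cholecalciferol	RX:2418
ferrous sulfate	Ferrous Sulfate	RX:4337
multivitamin	Multivitamin	RX:89905
pediasure	Pediatric Nutritional Supplement	RX:1234567
senna	Sennosides	RX:36387
sennosides	Sennosides	RX:36387
docusate	Docusate	RX:82003
colace	Docusate	RX:217020
simethicone	Simethicone	RX:9796
mylicon	Simethicone	RX:219426
erythromycin	Erythromycin	RX:4053
clindamycin	Clindamycin	RX:2582
cephalexin	Cephalexin	RX:2231
keflex	Cephalexin	RX:202934
insulin	Insulin	RX:5856
lantus	Insulin Glargine	RX:261542
metformin	Metformin	RX:6809
hydrocortisone	Hydrocortisone	RX:5492
amlodipine	Amlodipine	RX:17767
norvasc	Amlodipine	RX:58927
enalapril	Enalapril	RX:3827
furosemide	Furosemide	RX:4603
lasix	Furosemide	RX:202991
spironolactone	Spironolactone	RX:9997
sildenafil	Sildenafil	RX:136411
propranolol	Propranolol	RX:8787
atenolol	Atenolol	RX:1202
digoxin	Digoxin	RX:3407
aspirin	Aspirin	RX:1191
morphine	Morphine	RX:7052
oxycodone	Oxycodone	RX:7804
midazolam	Midazolam	RX:6960
versed	Midazolam	RX:203135
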