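generic,atc_code
fluoxetine,N
sertraline,N
paroxetine,N
citalopram,N
escitalopram,N
fluvoxamine,N
venlafaxine,N
duloxetine,N
desvenlafaxine,N
mirtazapine,N
trazodone,N
amitriptyline,N
clomipramine,N
nortriptyline,N
bupropion,N
lithium,N
buspirone,N
quetiapine,N
risperidone,N
olanzapine,N
aripiprazole,N
lamotrigine,N
lacosamide,N
gabapentin,N
pregabalin,N
tramadol,N
fentanyl,N
oxycodone,N
methadone,N
tapentadol,N
linezolid,J
ciprofloxacin,J
fluconazole,J
isoniazid,J
ondansetron,A
metoclopramide,A
granisetron,A
domperidone,A
metformin,A
omeprazole,A
cyclobenzaprine,M
baclofen,M
tizanidine,M
methocarbamol,M
isotretinoin,D
terbinafine,D
methylene blue,V
dextromethorphan,R
diphenhydramine,R
warfarin,B
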