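raw,generic
PROZAC,fluoxetine
SARAFEM,fluoxetine
ZOLOFT,sertraline
PAXIL,paroxetine
CELEXA,citalopram
LEXAPRO,escitalopram
LUVOX,fluvoxamine
EFFEXOR,venlafaxine
CYMBALTA,duloxetine
PRISTIQ,desvenlafaxine
REMERON,mirtazapine
DESYREL,trazodone
ELAVIL,amitriptyline
ANAFRANIL,clomipramine
PAMELOR,nortriptyline
WELLBUTRIN,bupropion
LITHOBID,lithium
BUSPAR,buspirone
SEROQUEL,quetiapine
RISPERDAL,risperidone
ZYPREXA,olanzapine
ABILIFY,aripiprazole
LAMICTAL,lamotrigine
VIMPAT,lacosamide
NEURONTIN,gabapentin
LYRICA,pregabalin
ULTRAM,tramadol
DURAGESIC,fentanyl
OXYCONTIN,oxycodone
DOLOPHINE,methadone
NUCYNTA,tapentadol
ZYVOX,linezolid
CIPRO,ciprofloxacin
DIFLUCAN,fluconazole
ZOFRAN,ondansetron
REGLAN,metoclopramide
KYTRIL,granisetron
MOTILIUM,domperidone
GLUCOPHAGE,metformin
PRILOSEC,omeprazole
FLEXERIL,cyclobenzaprine
LIORESAL,baclofen
ZANAFLEX,tizanidine
ROBAXIN,methocarbamol
ACCUTANE,isotretinoin
LAMISIL,terbinafine
PROVAYBLUE,methylene blue
DELSYM,dextromethorphan
BENADRYL,diphenhydramine
COUMADIN,warfarin
FLUOXETINE,fluoxetine
SERTRALINE,sertraline
PAROXETINE,paroxetine
CITALOPRAM,citalopram
ESCITALOPRAM,escitalopram
FLUVOXAMINE,fluvoxamine
VENLAFAXINE,venlafaxine
DULOXETINE,duloxetine
DESVENLAFAXINE,desvenlafaxine
MIRTAZAPINE,mirtazapine
TRAZODONE,trazodone
AMITRIPTYLINE,amitriptyline
CLOMIPRAMINE,clomipramine
NORTRIPTYLINE,nortriptyline
BUPROPION,bupropion
LITHIUM,lithium
BUSPIRONE,buspirone
QUETIAPINE,quetiapine
RISPERIDONE,risperidone
OLANZAPINE,olanzapine
ARIPIPRAZOLE,aripiprazole
LAMOTRIGINE,lamotrigine
LACOSAMIDE,lacosamide
GABAPENTIN,gabapentin
PREGABALIN,pregabalin
TRAMADOL,tramadol
FENTANYL,fentanyl
OXYCODONE,oxycodone
METHADONE,methadone
TAPENTADOL,tapentadol
LINEZOLID,linezolid
CIPROFLOXACIN,ciprofloxacin
FLUCONAZOLE,fluconazole
ISONIAZID,isoniazid
ONDANSETRON,ondansetron
METOCLOPRAMIDE,metoclopramide
GRANISETRON,granisetron
DOMPERIDONE,domperidone
METFORMIN,metformin
OMEPRAZOLE,omeprazole
CYCLOBENZAPRINE,cyclobenzaprine
BACLOFEN,baclofen
TIZANIDINE,tizanidine
METHOCARBAMOL,methocarbamol
ISOTRETINOIN,isotretinoin
TERBINAFINE,terbinafine
METHYLENE BLUE,methylene blue
DEXTROMETHORPHAN,dextromethorphan
DIPHENHYDRAMINE,diphenhydramine
WARFARIN,warfarin
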