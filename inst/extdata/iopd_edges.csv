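"source","target","weight","provenance"
OCT4,NANOG,0.8,"literature: core pluripotency circuit"
SOX2,NANOG,0.8,"literature: core pluripotency circuit"
KLF4,NANOG,0.3,"literature: reprogramming factor input"
cMYC,NANOG,0.3,"literature: reprogramming factor input"
NANOG,OCT4,0.8,"literature: core pluripotency circuit"
NANOG,SOX2,0.8,"literature: core pluripotency circuit"
OCT4,SOX2,0.4,"literature: core pluripotency circuit"
SOX2,OCT4,0.4,"literature: core pluripotency circuit"
NANOG,KLF4,0.4,"curated: closure edge"
NANOG,cMYC,0.4,"curated: closure edge"
NANOG,GDF3,0.6,"literature: undifferentiated ESC marker panel"
OCT4,GDF3,0.3,"literature: undifferentiated ESC marker panel"
NANOG,REX1,0.6,"literature: undifferentiated ESC marker panel"
OCT4,REX1,0.3,"literature: undifferentiated ESC marker panel"
NANOG,FGF4,0.6,"literature: undifferentiated ESC marker panel"
OCT4,FGF4,0.3,"literature: undifferentiated ESC marker panel"
NANOG,DPPA5,0.6,"literature: undifferentiated ESC marker panel"
OCT4,DPPA5,0.3,"literature: undifferentiated ESC marker panel"
NANOG,DPPA2,0.6,"literature: undifferentiated ESC marker panel"
OCT4,DPPA2,0.3,"literature: undifferentiated ESC marker panel"
NANOG,DPPA4,0.6,"literature: undifferentiated ESC marker panel"
OCT4,DPPA4,0.3,"literature: undifferentiated ESC marker panel"
NANOG,hTERT,0.6,"literature: undifferentiated ESC marker panel"
OCT4,hTERT,0.3,"literature: undifferentiated ESC marker panel"
NANOG,SALL4,0.6,"literature: undifferentiated ESC marker panel"
OCT4,SALL4,0.3,"literature: undifferentiated ESC marker panel"
NANOG,ECAD,0.6,"literature: undifferentiated ESC marker panel"
OCT4,ECAD,0.3,"literature: undifferentiated ESC marker panel"
NANOG,SSEA34,0.6,"literature: undifferentiated ESC marker panel"
OCT4,SSEA34,0.3,"literature: undifferentiated ESC marker panel"
NANOG,TRA_1_81,0.6,"literature: undifferentiated ESC marker panel"
OCT4,TRA_1_81,0.3,"literature: undifferentiated ESC marker panel"
NANOG,ALP,0.6,"literature: undifferentiated ESC marker panel"
OCT4,ALP,0.3,"literature: undifferentiated ESC marker panel"
MyoD1_exo,MyoD1,0.5,"literature: transgene induces endogenous program"
Doxycycline,MyoD1,0.2,"curated: closure edge"
Myogenin,MyoD1,0.4,"curated: closure edge"
NANOG,MyoD1,-0.9,"curated: closure edge"
OCT4,MyoD1,-0.9,"curated: closure edge"
MyoD1,NANOG,-0.6,"curated: closure edge"
MyoD1,OCT4,-0.6,"curated: closure edge"
MyoD1,SOX2,-0.6,"curated: closure edge"
MyoD1,Myogenin,0.8,"literature: myogenic differentiation cascade"
MyoD1,CKM,0.7,"literature: mature skeletal muscle marker"
Myogenin,CKM,0.5,"literature: mature skeletal muscle marker"
MyoD1,MyHC,0.7,"literature: mature skeletal muscle marker"
Myogenin,MyHC,0.5,"literature: mature skeletal muscle marker"
Fibroblast,Pax7,0.3,"curated: closure edge"
MyoD1,Pax7,-0.8,"literature: Pax7 down-regulated on MyoD1-driven differentiation"
Myogenin,Pax7,-0.5,"curated: closure edge"
Fibroblast,GAA,0.15,"curated: closure edge"
Fibroblast,lysosomal_glycogen,0.2,"curated: closure edge"
Fibroblast,mTORC1_p,0.4,"curated: closure edge"
Fibroblast,ATP,0.4,"curated: closure edge"
Fibroblast,lysosomal_calcium,0.2,"curated: closure edge"
Fibroblast,LAMP2,0.1,"curated: closure edge"
Doxycycline,mTORC1_p,0.2,"literature: tetracycline-class drugs act on PI3K-AKT-mTOR signalling"
GAA,lysosomal_glycogen,-1,"literature: GAA converts lysosomal glycogen to glucose"
lysosomal_glycogen,LAMP2,0.8,"literature: lysosomal expansion marker rises with glycogen load"
lysosomal_glycogen,glucose_deprivation,0.8,"literature: sequestered glycogen starves the cytosol of glucose"
GAA,glucose_deprivation,-0.4,"curated: closure edge"
lysosomal_glycogen,mTORC1_p,-0.9,"literature: mTORC1 activity suppressed with lysosomal glycogen accumulation"
mTORC1_p,p70S6K_p,0.9,"literature: direct mTORC1 substrate"
mTORC1_p,p4EBP1_p,0.9,"literature: direct mTORC1 substrate"
mTORC1_p,autophagy,-0.8,"literature: mTORC1 represses autophagy"
autophagy,LC3,0.8,"literature: autophagosome marker"
autophagy,p62,0.6,"literature: receptor accumulates when flux is incomplete"
lysosomal_glycogen,p62,0.3,"curated: closure edge"
mitochondrial_dysfunction,Pink2,0.8,"literature: mitophagy signalling on damaged mitochondria"
Pink2,mitophagy,0.7,"literature: mitophagy effector arm"
autophagy,mitophagy,0.4,"curated: closure edge"
glucose_deprivation,VDCC,0.7,"curated: closure edge"
calpain,VDCC,0.3,"curated: closure edge"
VDCC,intracellular_calcium,1,"literature: calcium influx via VDCC-class channels"
intracellular_calcium,calpain,0.9,"literature: calcium-activated protease"
calpain,cell_death,0.8,"literature: calpain overactivation is cytotoxic"
calpain,mitochondrial_dysfunction,0.7,"literature: calcium/calpain overload injures mitochondria"
lysosomal_glycogen,mitochondrial_dysfunction,0.3,"curated: closure edge"
glucose_deprivation,mitochondrial_dysfunction,0.3,"curated: closure edge"
mitochondrial_dysfunction,ROS,0.8,"literature: dysfunction raises reactive oxygen species"
mitochondrial_dysfunction,CytC,0.8,"literature: Cytochrome C release from damaged mitochondria"
mitochondrial_dysfunction,AIF,0.8,"literature: apoptosis-inducing factor release"
mitochondrial_dysfunction,ADP,0.9,"literature: ADP markedly elevated under impaired respiration"
mitochondrial_dysfunction,ATP,-0.9,"literature: reduced ATP generation"
mitochondrial_dysfunction,impaired_energy_metabolism,0.9,"literature: energy metabolism impaired as a dysfunction subnetwork"
mitochondrial_dysfunction,DNM1L,0.7,"literature: mitochondrial shaping protein elevated in disease"
mitochondrial_dysfunction,MFN2,0.7,"literature: mitochondrial shaping protein elevated in disease"
CytC,Caspase3,0.8,"literature: intrinsic apoptosis pathway"
AIF,Caspase3,0.3,"curated: closure edge"
Caspase3,apoptosis,0.9,"literature: executioner caspase"
apoptosis,cell_death,0.4,"literature: apoptotic death route"
glucose_deprivation,impaired_energy_metabolism,0.3,"curated: closure edge"
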