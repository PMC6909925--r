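"id","label","kind","aliases"
"Fibroblast","Fibroblast","phenotype",""
"lysosomal_glycogen","lysosomal_glycogen","phenotype",""
"glucose_deprivation","glucose_deprivation","phenotype",""
"mitochondrial_dysfunction","mitochondrial_dysfunction","phenotype",""
"impaired_energy_metabolism","impaired_energy_metabolism","phenotype",""
"apoptosis","apoptosis","phenotype",""
"cell_death","cell_death","phenotype",""
"autophagy","autophagy","phenotype",""
"mitophagy","mitophagy","phenotype",""
"Doxycycline","Doxycycline","compound","Dox"
"ATP","ATP","compound",""
"ADP","ADP","compound",""
"ROS","ROS","compound",""
"intracellular_calcium","intracellular_calcium","compound",""
"lysosomal_calcium","lysosomal_calcium","compound",""
"MyoD1_exo","MyoD1_exo","gene","exogenous MyoD1;MYOD1-transgene"
"MyoD1","MyoD1","gene","MYOD1;MyoD1-endogenous"
"OCT4","OCT4","gene","OCT3/4;POU5F1"
"SOX2","SOX2","gene",""
"KLF4","KLF4","gene",""
"cMYC","cMYC","gene","MYC;c-MYC"
"NANOG","NANOG","gene",""
"GDF3","GDF3","gene",""
"REX1","REX1","gene","ZFP42"
"FGF4","FGF4","gene",""
"DPPA5","DPPA5","gene","ESG1;ESG1/DPPA5"
"DPPA2","DPPA2","gene",""
"DPPA4","DPPA4","gene",""
"hTERT","hTERT","gene","TERT"
"SALL4","SALL4","gene",""
"CKM","CKM","gene",""
"Myogenin","Myogenin","gene","MYOG"
"Pax7","Pax7","gene",""
"GAA","GAA","gene",""
"ECAD","ECAD","protein","E-CADHERIN;CDH1"
"SSEA34","SSEA34","protein","SSEA-3/4;SSEA3;SSEA4"
"TRA_1_81","TRA_1_81","protein","TRA-1-81"
"ALP","ALP","protein","alkaline phosphatase"
"MyHC","MyHC","protein","myosin heavy chain"
"LAMP2","LAMP2","protein",""
"mTORC1_p","mTORC1_p","protein","mTORC1-p;p-mTORC1"
"p70S6K_p","p70S6K_p","protein","p70S6K-p"
"p4EBP1_p","p4EBP1_p","protein","p4EBP1-p"
"CytC","CytC","protein","Cytochrome C"
"AIF","AIF","protein",""
"Caspase3","Caspase3","protein",""
"DNM1L","DNM1L","protein",""
"MFN2","MFN2","protein",""
"LC3","LC3","protein","LC3/LC3-II;LC3-II;LCII"
"p62","p62","protein","SQSTM1;p62(SQSTM1)"
"Pink2","Pink2","protein",""
"VDCC","VDCC","protein",""
"calpain","calpain","protein",""
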