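protein_id,compartment,p_value
BCAR1,nucleus,0.0455
ELAVL1,cytoplasm,3.6e-5
NDRG1,plasma_membrane,0.1675
NDRG1,nucleus,0.1005
CCNEL,nucleus,0.8563
AHR,nucleus,0.0158
p68,cytoplasm,4.6e-7
EBP50,nucleus,0.0076
CDKN1B,cytoplasm,6.65e-8
CACYBP,nucleus,1.03e-5
ARRB1,plasma_membrane,1.12e-3
p53,cytoplasm,0.0498
p53,nucleus,0.0365
BRD4,nucleus,1.3e-5
AKT1,cytoplasm,0.0204
PRKCA,plasma_membrane,4.04e-11
SMAD3,nucleus,0.0249
HNRNPK,cytoplasm,3.46e-4
HNRNPK,nucleus,0.0110
PRKCB,plasma_membrane,0.0240
beta-catenin,cytoplasm,1.65e-4
beta-catenin,nucleus,2.86e-4
STAT3,nucleus,5.2e-5
TET2,cytoplasm,1.86e-3
BCL2,nucleus,0.2644
BCL2,plasma_membrane,0.1820
CYSLT1,nucleus,0.5582
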