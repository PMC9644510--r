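protein_id,level_normal,level_cancer,p_expression
BCAR1,medium,low,0.5437
ELAVL1,medium,high,0.7435
NDRG1,high,medium,3.37e-4
CCNEL,medium,low,0.0706
AHR,medium,low,0.0094
p68,medium,low,0.0029
EBP50,high,medium,0.1086
CDKN1B,medium,low,2.14e-3
CACYBP,medium,high,2.85e-7
ARRB1,high,low,0.5986
p53,high,medium,9.34e-3
BRD4,high,low,0.0376
AKT1,medium,low,1.04e-3
PRKCA,medium,low,2.13e-3
SMAD3,medium,low,0.0225
HNRNPK,high,low,0.1058
PRKCB,low,high,0.3276
beta-catenin,medium,low,0.6826
STAT3,medium,low,5.88e-4
TET2,medium,high,0.0491
BCL2,low,medium,0.0203
CYSLT1,low,medium,0.0178
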