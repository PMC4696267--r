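molecule_id,target_id,ec50_uM
ethanol,TEX1,50
acetic_acid,TEX1,22
benzene,TEX1,0.4
toluene,TEX1,0.6
pyridine,TEX1,0.9
pyrrole,TEX1,1.4
aspirin,TEX1,0.2
caffeine,TEX1,3.5
ibuprofen,TEX1,0.08
paracetamol,TEX1,0.7
glycerol,TEX1,120
cyclohexane,TEX1,85
salicylic_acid,TEX1,0.3
triethylamine,TEX1,40
methionine_like,TEX1,15
benzamide,TEX1,2.1
chlorobenzene,TEX1,1.8
citric_acid,TEX1,60
amphetamine_like,TEX1,5.5
benzenesulfonamide,TEX1,4.2
aspirin,TEX2,12
caffeine,TEX2,0.5
ibuprofen,TEX2,30
paracetamol,TEX2,0.9
benzamide,TEX2,0.3
salicylic_acid,TEX2,18
pyridine,TEX2,0.6
pyrrole,TEX2,0.8
toluene,TEX2,25
benzene,TEX2,40
chlorobenzene,TEX2,2.2
benzenesulfonamide,TEX2,0.7
amphetamine_like,TEX2,1.1
triethylamine,TEX2,75
glycerol,TEX2,200
cyclohexane,TEX2,150
ethanol,TEX2,90
acetic_acid,TEX2,66
citric_acid,TEX2,110
methionine_like,TEX2,9
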