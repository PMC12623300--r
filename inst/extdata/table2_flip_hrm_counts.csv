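hrm_row,block,Normal,Hypo-contractility,Non-spastic obstruction,Spastic obstruction,Possible spasm,Possible obstruction
Normal,Conclusive CCv4.0 Diagnosis,111,21,10,13,33,76
IEM,Conclusive CCv4.0 Diagnosis,16,22,2,4,12,32
Absent,Conclusive CCv4.0 Diagnosis,2,34,1,2,1,5
DES,Conclusive CCv4.0 Diagnosis,2,0,0,1,0,6
Hypercontractile,Conclusive CCv4.0 Diagnosis,4,0,2,8,4,11
EGJOO,Conclusive CCv4.0 Diagnosis,2,0,9,7,0,10
Type I achalasia,Conclusive CCv4.0 Diagnosis,0,0,50,2,1,19
Type II achalasia,Conclusive CCv4.0 Diagnosis,0,1,76,22,0,33
Type III achalasia,Conclusive CCv4.0 Diagnosis,0,0,13,16,0,8
Inconclusive EGJOO,Inconclusive CCv4.0 Diagnosis,19,6,9,21,11,32
Inconclusive,Inconclusive CCv4.0 Diagnosis,0,0,2,0,0,1
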