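description,antecedent,consequent,weight,connection
pH = Excessive-Acid => Unproductive,1;0;0;0;0;0;0;0;0;0;0;0,1,1,AND
EC = Strongly-Saline => Unproductive,0;0;4;0;0;0;0;0;0;0;0;0,1,1,AND
OM = Low & N = Low => Unproductive,0;1;0;1;0;0;0;0;0;0;0;0,1,1,AND
Zn = Low & B = Low => Unproductive,0;0;0;0;0;0;0;0;1;1;0;0,1,1,AND
pH = Acid => Low,2;0;0;0;0;0;0;0;0;0;0;0,2,1,AND
OM = Low => Low,0;1;0;0;0;0;0;0;0;0;0;0,2,1,AND
EC = Slightly-Saline & N = Low => Low,0;0;2;1;0;0;0;0;0;0;0;0,2,1,AND
P = Low & K = Sufficient => Low,0;0;0;0;1;2;0;0;0;0;0;0,2,1,AND
pH = Neutral => Medium,3;0;0;0;0;0;0;0;0;0;0;0,3,1,AND
OM = Medium => Medium,0;2;0;0;0;0;0;0;0;0;0;0,3,1,AND
EC = Non-saline & N = Sufficient => Medium,0;0;1;2;0;0;0;0;0;0;0;0,3,1,AND
pH = Neutral & OM = Medium & EC = Non-saline => Medium,3;2;1;0;0;0;0;0;0;0;0;0,3,1,AND
pH = Neutral & OM = High & N = High => Productive,3;3;0;3;0;0;0;0;0;0;0;0,4,1,AND
EC = Non-saline & P = High & K = High => Productive,0;0;1;0;3;3;0;0;0;0;0;0,4,1,AND
OM = Very-high & EC = Non-saline & N = High & K = High => Productive,0;4;1;3;0;3;0;0;0;0;0;0,4,1,AND
Fe = Medium & Zn = High & B = High => Productive,0;0;0;0;0;0;2;0;3;3;0;0,4,1,AND
pH = Acid & OM = Low & N = Low => Low,2;1;0;1;0;0;0;0;0;0;0;0,2,1,AND
pH = Neutral & P = Low & K = Low => Low,3;0;0;0;1;1;0;0;0;0;0;0,2,1,AND
pH = Alkaline & OM = Medium & N = Sufficient => Medium,4;2;0;2;0;0;0;0;0;0;0;0,3,1,AND
EC = Strongly-Saline & Zn = Low & Mn = Low => Low,0;0;4;0;0;0;0;1;1;0;0;0,2,1,AND
OM = High & Fe = High & Cu = Medium => Productive,0;3;0;0;0;0;3;0;0;0;2;0,4,1,AND
N = Low & P = Sufficient & K = High => Medium,0;0;0;1;2;3;0;0;0;0;0;0,3,1,AND
B = Low & Cu = Low & Mn = Low => Low,0;0;0;0;0;0;0;1;0;1;1;0,2,1,AND
P = High & K = High & Zn = High => Productive,0;0;0;0;3;3;0;0;3;0;0;0,4,1,AND
EC = Slightly-Saline & Fe = Medium & B = Low => Medium,0;0;2;0;0;0;2;0;0;1;0;0,3,1,AND
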