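sex,age_low,age_high,quantity,pal,reference_value,unit
male,3,4,energy,low,1100,kcal/day
male,4,7,energy,low,1250,kcal/day
male,7,10,energy,low,1500,kcal/day
male,10,13,energy,low,1850,kcal/day
male,13,15,energy,low,2150,kcal/day
male,15,19,energy,low,2500,kcal/day
female,3,4,energy,low,1000,kcal/day
female,4,7,energy,low,1150,kcal/day
female,7,10,energy,low,1350,kcal/day
female,10,13,energy,low,1700,kcal/day
female,13,15,energy,low,1900,kcal/day
female,15,19,energy,low,2000,kcal/day
male,3,4,protein,,14,g/day
male,4,7,protein,,18,g/day
male,7,10,protein,,26,g/day
male,10,13,protein,,37,g/day
male,13,15,protein,,50,g/day
male,15,19,protein,,62,g/day
female,3,4,protein,,14,g/day
female,4,7,protein,,18,g/day
female,7,10,protein,,26,g/day
female,10,13,protein,,38,g/day
female,13,15,protein,,49,g/day
female,15,19,protein,,48,g/day
male,3,4,vitamin_b2,,0.7,mg/day
male,4,7,vitamin_b2,,0.8,mg/day
male,7,10,vitamin_b2,,1.0,mg/day
male,10,13,vitamin_b2,,1.4,mg/day
male,13,15,vitamin_b2,,1.6,mg/day
male,15,19,vitamin_b2,,1.6,mg/day
female,3,4,vitamin_b2,,0.7,mg/day
female,4,7,vitamin_b2,,0.8,mg/day
female,7,10,vitamin_b2,,0.9,mg/day
female,10,13,vitamin_b2,,1.1,mg/day
female,13,15,vitamin_b2,,1.3,mg/day
female,15,19,vitamin_b2,,1.2,mg/day
male,3,4,vitamin_b12,,1.5,ug/day
male,4,7,vitamin_b12,,2.0,ug/day
male,7,10,vitamin_b12,,2.5,ug/day
male,10,13,vitamin_b12,,3.5,ug/day
male,13,15,vitamin_b12,,4.0,ug/day
male,15,19,vitamin_b12,,4.0,ug/day
female,3,4,vitamin_b12,,1.5,ug/day
female,4,7,vitamin_b12,,2.0,ug/day
female,7,10,vitamin_b12,,2.5,ug/day
female,10,13,vitamin_b12,,3.5,ug/day
female,13,15,vitamin_b12,,4.0,ug/day
female,15,19,vitamin_b12,,4.0,ug/day
male,3,4,calcium,,600,mg/day
male,4,7,calcium,,750,mg/day
male,7,10,calcium,,900,mg/day
male,10,13,calcium,,1100,mg/day
male,13,15,calcium,,1200,mg/day
male,15,19,calcium,,1200,mg/day
female,3,4,calcium,,600,mg/day
female,4,7,calcium,,750,mg/day
female,7,10,calcium,,900,mg/day
female,10,13,calcium,,1100,mg/day
female,13,15,calcium,,1200,mg/day
female,15,19,calcium,,1200,mg/day
male,3,4,iron,,8,mg/day
male,4,7,iron,,8,mg/day
male,7,10,iron,,10,mg/day
male,10,13,iron,,12,mg/day
male,13,15,iron,,12,mg/day
male,15,19,iron,,12,mg/day
female,3,4,iron,,8,mg/day
female,4,7,iron,,8,mg/day
female,7,10,iron,,10,mg/day
female,10,13,iron,,15,mg/day
female,13,15,iron,,15,mg/day
female,15,19,iron,,15,mg/day
male,3,4,iodine,,100,ug/day
male,4,7,iodine,,120,ug/day
male,7,10,iodine,,140,ug/day
male,10,13,iodine,,180,ug/day
male,13,15,iodine,,200,ug/day
male,15,19,iodine,,200,ug/day
female,3,4,iodine,,100,ug/day
female,4,7,iodine,,120,ug/day
female,7,10,iodine,,140,ug/day
female,10,13,iodine,,180,ug/day
female,13,15,iodine,,200,ug/day
female,15,19,iodine,,200,ug/day
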