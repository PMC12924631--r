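nutrient,class,units,gilt,barrow,boar
sodium,mineral,g/d,2.92,2.94,2.90
chlorine,mineral,g/d,2.31,2.32,2.29
magnesium,mineral,g/d,1.15,1.16,1.14
potassium,mineral,g/d,4.75,4.76,4.73
copper,mineral,mg/d,8.46,8.48,8.41
iodine,mineral,mg/d,0.40,0.40,0.40
iron,mineral,mg/d,111.34,111.52,110.96
manganese,mineral,mg/d,5.79,5.82,5.74
selenium,mineral,mg/d,0.41,0.42,0.41
zinc,mineral,mg/d,140.96,141.45,139.91
vitamin_a,vitamin,IU/d,3767.85,3784.44,3732.48
vitamin_d3,vitamin,IU/d,434.76,436.67,430.68
vitamin_e,vitamin,IU/d,31.88,32.02,31.58
vitamin_k,vitamin,mg/d,1.44,1.45,1.43
biotin,vitamin,mg/d,0.14,0.14,0.14
choline,vitamin,g/d,0.86,0.87,0.86
folacin,vitamin,mg/d,0.86,0.87,0.86
niacin,vitamin,mg/d,86.95,87.33,86.13
pantothenic_acid,vitamin,mg/d,19.89,19.96,19.73
riboflavin,vitamin,mg/d,5.59,5.61,5.56
thiamin,vitamin,mg/d,2.89,2.91,2.87
vitamin_b6,vitamin,mg/d,2.89,2.91,2.87
vitamin_b12,vitamin,ug/d,12.51,12.50,12.53
linoleic_acid,vitamin,g/d,2.89,2.91,2.87
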