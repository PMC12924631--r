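nutrient,class,units,intercept,slope
biotin,vitamin,mg/d,0.14,0
chlorine,mineral,g/d,-1.7907456985248,0.847200877587916
choline,vitamin,g/d,-0.292876906050219,0.239063643631121
copper,mineral,mg/d,-1.215425793287,1.99847037215425
folacin,vitamin,mg/d,-0.292876906050219,0.239063643631121
iodine,mineral,mg/d,0.4,0
iron,mineral,mg/d,34.578708634078,15.8577530305395
linoleic_acid,vitamin,g/d,-2.36362260457505,1.08626452121904
magnesium,mineral,g/d,-1.47681130228752,0.543132260609521
manganese,mineral,mg/d,-5.03830269933717,2.23753401578536
niacin,vitamin,mg/d,-77.7219429213677,34.0180450502115
pantothenic_acid,vitamin,mg/d,-11.7630886821484,6.53854337707225
potassium,mineral,g/d,0.649254301475264,0.847200877587902
riboflavin,vitamin,mg/d,-1.13755700081243,1.39033313819746
selenium,mineral,mg/d,-0.742876906050219,0.239063643631121
sodium,mineral,g/d,-2.33362260457505,1.08626452121904
thiamin,vitamin,mg/d,-2.36362260457505,1.08626452121904
vitamin_a,vitamin,IU/d,-3358.07874662865,1472.09728303663
vitamin_b12,vitamin,ug/d,16.6107456985247,-0.847200877587902
vitamin_b6,vitamin,mg/d,-2.36362260457505,1.08626452121904
vitamin_d3,vitamin,IU/d,-386.804722720412,169.721151660731
vitamin_e,vitamin,IU/d,-28.4783085718227,12.4689495201878
vitamin_k,vitamin,mg/d,-1.18681130228752,0.543132260609521
zinc,mineral,mg/d,-70.2940800013769,43.6413233206568
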