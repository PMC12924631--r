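quantity,units,gilt,barrow,boar
bw,kg,126.55,127.99,123.55
sid_lysine,g/d,17.65,17.31,19.47
arginine,g/d,8.06,7.91,8.90
histidine,g/d,6.06,5.95,6.70
isoleucine,g/d,9.21,9.03,10.16
leucine,g/d,17.76,17.43,19.61
methionine,g/d,5.09,5.00,5.62
methionine_cysteine,g/d,9.95,9.76,10.98
phenylalanine,g/d,10.53,10.33,11.62
phenylalanine_tyrosine,g/d,16.55,16.24,18.27
threonine,g/d,10.64,10.44,11.74
tryptophan,g/d,3.01,2.96,3.33
valine,g/d,11.45,11.23,12.64
nitrogen,g/d,37.90,37.19,41.83
sttd_p,g/d,5.34,5.08,6.22
total_ca,g/d,11.49,10.92,13.38
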