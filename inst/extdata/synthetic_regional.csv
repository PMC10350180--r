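"region","mean_volume","mean_density"
"R01",0.0743,0.4178
"R02",0.017,0.5957
"R03",0.0701,0.1147
"R04",0.0726,0.0547
"R05",0.1387,0.5359
"R06",0.0489,0.2156
"R07",0.1233,0.321
"R08",0.1171,0.3253
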