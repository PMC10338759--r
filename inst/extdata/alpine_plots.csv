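plot,avg_height_m,n_trees,stem_density,area_m2
01,17,359,0.04,10000
02,18,106,0.08,1300
03,17,49,0.04,1300
04,13,22,0.02,1300
06,14,107,0.04,3000
07,16,49,0.04,1300
15,23,53,0.03,2000
16,25,37,0.02,2000
17,21,117,0.06,2000
18,25,92,0.05,2000
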