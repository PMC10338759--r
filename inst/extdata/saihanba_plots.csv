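plot,tree_type,avg_height_m,n_trees,stem_density,point_density,area_m2
P1,birch,15,122,0.14,298,900
P2,mixed,18,89,0.10,3295,900
P3,larch,21,121,0.05,1636,2500
P4,spruce,15,87,0.10,1473,900
P5,mongolian_pine,16,87,0.10,3976,900
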