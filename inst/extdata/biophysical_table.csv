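"class","name","k_c","c_above","c_below","c_soil","c_dead","habitat","sens_builtup","sens_farmland","usle_c","usle_p"
1,"farmland",0.65,5,8,90,1,0.4,0.5,0,0.22,0.4
2,"forest",1,120,30,140,10,1,0.9,0.6,0.003,1
3,"grassland",0.85,8,20,100,2,0.7,0.7,0.5,0.05,1
4,"water",1.1,0,0,0,0,0.9,0.6,0.4,0,0
5,"builtup",0.3,2,1,30,0,0,0,0,0,0
6,"unused",0.5,1,1,40,0,0.3,0.4,0.2,0.35,1
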