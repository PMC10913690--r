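boundary,vertex,ref_mgdl,est_mgdl
ab_upper,1,0,50
ab_upper,2,30,50
ab_upper,3,140,170
ab_upper,4,280,380
ab_upper,5,430,550
bc_upper,1,0,60
bc_upper,2,30,60
bc_upper,3,50,80
bc_upper,4,70,110
bc_upper,5,260,550
cd_upper,1,0,100
cd_upper,2,25,100
cd_upper,3,50,125
cd_upper,4,80,215
cd_upper,5,125,550
de_upper,1,0,150
de_upper,2,35,155
de_upper,3,50,550
ab_lower,1,50,0
ab_lower,2,50,30
ab_lower,3,170,145
ab_lower,4,385,300
ab_lower,5,550,450
bc_lower,1,120,0
bc_lower,2,120,30
bc_lower,3,260,130
bc_lower,4,550,250
cd_lower,1,250,0
cd_lower,2,250,40
cd_lower,3,550,150
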