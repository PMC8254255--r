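id,name,node_id,urban,pop_0_14,pop_15_64,pop_65plus,current_stations,current_als
M1,Alba,n1,TRUE,4200,19300,3500,2,1
M2,Breznik,n2,FALSE,310,1450,260,1,0
M3,Cierna,n3,FALSE,120,780,190,0,0
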