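cell_id,node_id,municipality_id,weight
c1_1,n1,M1,15000
c1_2,n1,M1,12000
c2_1,n2,M2,2020
c3_1,n3,M3,1090
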