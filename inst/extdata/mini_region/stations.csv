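id,node_id,type
S1,n1,ALS
S2,n1,BLS
S3,n2,BLS
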