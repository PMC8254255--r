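id,node_id,specializations,dropoff_shape,dropoff_mean
H1,n1,general;cardio;pediatric,3,18.5
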