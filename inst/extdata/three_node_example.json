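{"n_sensors":0,"n_hidden":3,"n_motors":0,"tpm":[0,6,5,3,0,4,4,0],"cm":[[0,1,1],[1,0,1],[1,1,0]]}
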