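{"n_sensors":2,"n_hidden":4,"n_motors":2,"tpm":[32,224,160,160,56,184,184,248,52,244,180,148,44,172,172,236,96,224,224,160,112,240,176,176,112,240,240,144,96,224,160,128,32,224,160,160,56,184,184,248,52,244,180,180,44,172,172,236,96,224,224,160,112,240,176,176,112,240,240,144,96,224,160,128,32,224,160,160,56,184,184,248,52,244,180,148,44,172,172,236,96,224,224,160,112,240,176,176,112,240,240,144,96,224,160,128,32,224,160,160,56,184,184,248,52,244,180,180,44,172,172,236,96,224,224,160,112,240,176,176,112,240,240,144,96,224,160,128,32,224,160,160,56,184,184,248,52,244,180,148,44,172,172,236,96,224,224,160,112,240,176,176,112,240,240,144,96,224,160,128,32,224,160,160,56,184,184,248,52,244,180,180,44,172,172,236,96,224,224,160,112,240,176,176,112,240,240,144,96,224,160,128,32,224,160,160,56,184,184,248,52,244,180,148,44,172,172,236,96,224,224,160,112,240,176,176,112,240,240,144,96,224,160,128,32,224,160,160,56,184,184,248,52,244,180,180,44,172,172,236,96,224,224,160,112,240,176,176,112,240,240,144,96,224,160,128],"cm":[[0,0,0,0,0,1,1,1],[0,0,0,0,0,1,1,1],[0,0,0,1,1,1,1,0],[0,0,1,0,1,1,0,0],[0,0,1,1,0,1,1,0],[0,0,0,0,0,1,0,0],[0,0,0,0,0,0,0,0],[0,0,0,0,0,0,0,0]]}
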