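class,sample_1,sample_2,sample_3,sample_4,sample_5,sample_6,sample_7,sample_8,sample_9
RBC,1,0,0,0,0,0,0,0,0
T,0,80,201,37,4,13,55,44,101
B,3,48,201,103,125,72,64,282,700
M,0,0,1,0,1,0,0,1,0
Macro,0,1,0,0,1,0,0,0,2
CTC,132,9,49,27,168,17,39,21,77
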