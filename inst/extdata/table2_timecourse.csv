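time_step,RBC,T,B,M,Macro,CTC
1,0.00,25.71,47.14,1.43,0.00,25.71
2,0.00,0.46,11.06,0.00,0.46,88.02
3,0.00,0.00,0.00,0.00,0.00,100.00
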