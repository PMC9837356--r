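frame_start_s,frame_end_s,frontal,cerebellum
0,30,1.25,0.75
30,60,4.5,3.25
60,120,7.125,5.5
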