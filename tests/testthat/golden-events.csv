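animal,segment,onset_frame,peak_frame,onset_s,peak_s,amplitude_pct
NAIVE_01,pre,120,124,6.000,6.200,0.215000
NAIVE_01,pos,2047,2051,102.350,102.550,0.040000
TR_03,vds,1201,1205,60.050,60.250,1.002345
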