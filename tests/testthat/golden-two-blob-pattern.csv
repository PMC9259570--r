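0.00000000000000e+00,0.00000000000000e+00,0.00000000000000e+00,5.51412839209348e-01,0.00000000000000e+00,0.00000000000000e+00,0.00000000000000e+00,0.00000000000000e+00,0.00000000000000e+00,0.00000000000000e+00
0.00000000000000e+00,6.41760832216174e-01,8.12703705688111e-01,6.89475031183178e-01,0.00000000000000e+00,0.00000000000000e+00,0.00000000000000e+00,0.00000000000000e+00,0.00000000000000e+00,0.00000000000000e+00
0.00000000000000e+00,8.12703705688111e-01,1.00000000000000e+00,8.25841199499180e-01,0.00000000000000e+00,0.00000000000000e+00,0.00000000000000e+00,0.00000000000000e+00,0.00000000000000e+00,0.00000000000000e+00
5.51412839209348e-01,6.89475031183179e-01,8.25841199499180e-01,6.75513789923608e-01,0.00000000000000e+00,0.00000000000000e+00,0.00000000000000e+00,0.00000000000000e+00,0.00000000000000e+00,0.00000000000000e+00
0.00000000000000e+00,0.00000000000000e+00,0.00000000000000e+00,0.00000000000000e+00,0.00000000000000e+00,0.00000000000000e+00,0.00000000000000e+00,0.00000000000000e+00,0.00000000000000e+00,0.00000000000000e+00
0.00000000000000e+00,0.00000000000000e+00,0.00000000000000e+00,0.00000000000000e+00,0.00000000000000e+00,0.00000000000000e+00,0.00000000000000e+00,0.00000000000000e+00,0.00000000000000e+00,0.00000000000000e+00
0.00000000000000e+00,0.00000000000000e+00,0.00000000000000e+00,0.00000000000000e+00,0.00000000000000e+00,0.00000000000000e+00,0.00000000000000e+00,0.00000000000000e+00,0.00000000000000e+00,0.00000000000000e+00
0.00000000000000e+00,0.00000000000000e+00,0.00000000000000e+00,0.00000000000000e+00,0.00000000000000e+00,0.00000000000000e+00,0.00000000000000e+00,5.13707849367700e-01,0.00000000000000e+00,0.00000000000000e+00
0.00000000000000e+00,0.00000000000000e+00,0.00000000000000e+00,0.00000000000000e+00,0.00000000000000e+00,0.00000000000000e+00,0.00000000000000e+00,0.00000000000000e+00,0.00000000000000e+00,0.00000000000000e+00
0.00000000000000e+00,0.00000000000000e+00,0.00000000000000e+00,0.00000000000000e+00,0.00000000000000e+00,0.00000000000000e+00,0.00000000000000e+00,0.00000000000000e+00,0.00000000000000e+00,0.00000000000000e+00
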