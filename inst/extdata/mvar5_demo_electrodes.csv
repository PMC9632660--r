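"label","x_mm","y_mm","z_mm","resected"
"X1",10,0,0,0
"X2",10,10,10,0
"X3",0,0,0,0
"X4",10,0,10,1
"X5",0,0,10,1
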