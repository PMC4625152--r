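diameter_nm,label,role,value,sd
10,Au-PEG-FB50 + FOCUS,target,532,79.4
10,Au-PEG-MUC + FOCUS,control,38,15.0
10,Au-PEG-FB50 + NIH/3t3,control,61,33.6
50,Au-PEG-FB50 + FOCUS,target,1460,252.8
50,Au-PEG-MUC + FOCUS,control,192,101.0
50,Au-PEG-FB50 + NIH/3t3,control,46,14.1
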