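label,value,sd
Au-cit,6.9,1.16
Au-PEG-COOH,0.1,0.05
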