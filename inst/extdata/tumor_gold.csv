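label,compartment,value,sd
Au-PEG-COOH,tumor,18,7.0
Au-PEG-FB50 tumor 1,tumor,26,3.3
Au-PEG-FB50 tumor 2,tumor,24,1.0
Au-PEG-COOH,liver,25,0.2
Au-PEG-FB50 tumor 1,liver,23,0.6
Au-PEG-FB50 tumor 2,liver,23,0.6
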