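organ,agent,mass,sd
liver,Au-PEG-COOH,115,1.1
liver,Au-PEG-FB50,38,0.5
kidneys,Au-PEG-COOH,3,0.1
kidneys,Au-PEG-FB50,3,0.1
spleen,Au-PEG-COOH,30,0.1
spleen,Au-PEG-FB50,13,0.1
lungs,Au-PEG-COOH,1,0.1
lungs,Au-PEG-FB50,0,0.1
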