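organ,absorbance_pct,absorbance_sd,scatter_pct,scatter_sd
liver,2.8,1.26,23.0,14.13
kidneys,0.0,7.89,6.4,11.91
spleen,4.3,8.34,5.1,29.81
lungs,1.1,9.09,0.9,31.52
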