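mix,theoretical_conc,theoretical_ratio,measured_conc,measured_ratio
Mix-1,2.52e12,0.3323,2.58e12,0.3276
Mix-2,1.60e12,0.0793,1.68e12,0.0715
Mix-3,1.48e12,0.0362,1.57e12,0.0362
Mix-4,1.45e12,0.0241,1.52e12,0.0237
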