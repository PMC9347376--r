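experiment,injection,VP4,VP1,VP2,VP0,VP3
Exp-1/Sys-1,INJ-1,4.336,5.669,7.076,7.523,8.769
Exp-1/Sys-1,INJ-2,4.334,5.669,7.088,7.536,8.782
Exp-1/Sys-1,INJ-3,4.336,5.670,7.073,7.522,8.775
Exp-2/Sys-2,INJ-1,4.374,5.696,7.163,7.627,8.911
Exp-2/Sys-2,INJ-2,4.370,5.691,7.158,7.624,8.913
Exp-2/Sys-2,INJ-3,4.375,5.697,7.171,7.641,8.924
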