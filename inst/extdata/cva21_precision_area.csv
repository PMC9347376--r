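experiment,injection,VP4,VP1,VP2,VP0,VP3,conc_per_ml
Exp-1/Sys-1,INJ-1,193564,22588588,21890324,11698177,17846286,3.66e12
Exp-1/Sys-1,INJ-2,193956,22455981,22072816,11671564,17881673,3.67e12
Exp-1/Sys-1,INJ-3,200811,22184617,22064813,11447195,17769682,3.64e12
Exp-2/Sys-2,INJ-1,179236,22026203,21541602,11979694,17320598,3.61e12
Exp-2/Sys-2,INJ-2,183989,22140644,21649730,12036562,17416280,3.63e12
Exp-2/Sys-2,INJ-3,186503,21690748,21647757,12123676,17060923,3.59e12
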