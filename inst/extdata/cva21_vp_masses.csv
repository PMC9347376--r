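name,calculated,observed
VP0,37183,37418
VP1,33231,33230
VP2,29897,29922
VP3,26546,26591
VP4,7304,7516
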