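heart,sex,trabecular_volume_pct,n_false_tendons_geq_1cm,avg_lv_thickness_cm
A,M,16.3,3,0.85
B,M,9.6,0,0.83
C,F,8.7,4,0.58
D,F,10.4,3,0.76
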