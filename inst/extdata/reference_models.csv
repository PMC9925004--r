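heart,sex,geometry,myocardial_volume_cm3,mesh_elements_million,mesh_points_million
A,M,detailed,394.2,86,14
A,M,smoothed,329.8,72,12
B,M,detailed,199.6,43,7
B,M,smoothed,180.5,39,6
C,F,detailed,170.6,37,6
C,F,smoothed,155.8,34,5
D,F,detailed,299.2,65,11
D,F,smoothed,268,58,10
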