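heart,geometry,sex,QRS,QRS_diff,CV,QT,QT_diff,TAT,TAT10,TAT90,EDI
A,detailed,M,97,-1,90,349,42,104.3,12.3,66.8,20.1
A,detailed,F,96,NA,90,391,NA,104.3,12.3,66.8,20.1
A,smoothed,M,99,2,80,339,28,99.8,13.8,71.3,21.3
A,smoothed,F,101,NA,80,367,NA,100.0,13.8,70.8,21.3
B,detailed,M,95,0,81,339,37,96.6,9.3,64.8,20.2
B,detailed,F,95,NA,86,376,NA,96.5,9.3,64.8,20.2
B,smoothed,M,83,1,88,335,63,84.4,10.8,59.8,18.1
B,smoothed,F,84,NA,86,367,NA,84.4,10.8,59.8,18.1
C,detailed,M,90,3,83,337,27,92.5,7.3,58.3,18.8
C,detailed,F,93,NA,84,364,NA,92.6,7.3,58.3,18.8
C,smoothed,M,93,1,85,329,30,94.4,9.8,60.3,19
C,smoothed,F,94,NA,86,359,NA,94.5,9.8,60.3,19
D,detailed,M,104,4,85,357,34,119.2,11.3,67.8,21.3
D,detailed,F,108,NA,83,391,NA,119.3,11.3,67.8,21.4
D,smoothed,M,99,5,86,359,40,120.6,11.8,71.3,22.6
D,smoothed,F,104,NA,86,399,NA,120.5,11.8,71.8,22.6
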