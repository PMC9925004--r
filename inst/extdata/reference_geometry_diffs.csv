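heart,sex,QRS_Gdiff,CV_Gdiff,QT_Gdiff,TAT_Gdiff,TAT10_Gdiff,TAT90_Gdiff,EDI_Gdiff
A,M,-2,10,10,4.5,-1.5,-4.5,-1.2
A,F,-5,10,24,4.3,-1.5,-4,-1.2
B,M,12,-7,4,12.2,-1.5,5,2.1
B,F,11,0,9,12.1,-1.5,5,2.1
C,M,-3,-2,8,-1.9,-2.5,-2,-0.2
C,F,-1,-2,5,-1.9,-2.5,-2,-0.2
D,M,5,-1,-2,-1.4,0.5,-3.5,-1.3
D,F,4,-3,-8,-1.2,0.5,-4,-1.2
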