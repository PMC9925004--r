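geometry,sex,site,events,simulations
detailed,F,RV_apex,2,13
detailed,F,RVOT,0,12
detailed,F,LV_apex,0,8
smoothed,F,RV_apex,1,11
smoothed,F,RVOT,2,10
smoothed,F,LV_apex,0,8
detailed,M,RV_apex,4,10
detailed,M,RVOT,7,15
detailed,M,LV_apex,6,10
smoothed,M,RV_apex,2,10
smoothed,M,RVOT,1,9
smoothed,M,LV_apex,1,10
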