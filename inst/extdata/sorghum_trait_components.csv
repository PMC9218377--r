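trait,kind,units,mean,PV,GV,EV
SF,count,percent,4.4,0.7,0.3,0.5
SB,count,percent,23.6,1.6,0.5,1.1
PHT,quantitative,cm,256.6,4577.7,4531.0,46.7
PNL,quantitative,cm,23.7,46.1,44.4,1.7
PNW,quantitative,cm,5.8,1.1,0.8,0.3
RNM,quantitative,number,52,178.0,153.3,24.7
DTF,quantitative,days,80.3,184.4,181.0,3.4
GRF,quantitative,days,39.7,20.0,15.6,4.4
DTM,quantitative,days,120.1,185.3,183.5,1.8
YLD,quantitative,kg/ha,2909.3,925968.9,708783.5,217185.4
HSW,quantitative,g,2.1,0.4,0.3,0.1
Fe,quantitative,ppm,37.5,69.6,37,32.6
Zn,quantitative,ppm,18,18,11.5,6.5
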