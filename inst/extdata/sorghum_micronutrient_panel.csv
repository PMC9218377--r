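genotype,role,Fe,Zn,YLD
Tanzania Acc#42,test,65.5,10.2,3315.3
Tanzania Acc#8,test,64.7,26.3,579.8
IS 3790,test,63.5,24.6,1332.0
IS 30310,test,63.3,26.4,3534.2
SUDAN COLL# 7 LODOKA,test,61.3,25.0,685.9
IS 12750,test,48.2,32.5,2178.8
ICSA 735,test,43.5,31.0,2741.1
SESO3,check,41.4,18.3,3238.1
NAROSORG2,check,34.5,16.6,3707.1
SESO1,check,33.8,18.1,3298.7
NAROSORG3,check,33.1,16.0,3714.1
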