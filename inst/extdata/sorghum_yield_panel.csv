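genotype,role,YLD
GBK 000955,test,4899.9
GE/30/1/2013A,test,4873.0
SILA,test,4811.7
GBK 034699,test,4776.3
GBK 044111,test,4763.0
GBK 043040,test,4723.1
GBK-051589,test,4692.2
GBK 000445,test,4677.9
GBK-051521,test,4646.1
Epuripur,test,4626.9
IS 26962-2,test,4580.8
SUDAN COLL # 40 LOWOI KUDO PAYAM,test,4523.3
GBK 044117,test,4498.9
Tanzania Acc#38,test,4494.7
Tanzania Acc#21,test,4485.6
SRS2708/8/2013A,test,4438.6
GBK 00046,test,4404.2
SRS2708/5/2013A,test,4396.7
GBK 034640,test,4393.5
GBK 034598,test,4375.0
Tanzania Acc#18,test,4352.9
GBK-051524,test,4339.1
IS 26962,test,4306.6
IESV23007DL,test,4259.0
GBK 043975,test,4250.1
SRS1108/SE3/2014A/E,test,4243.3
GBK-051515,test,4226.6
Tanzania Acc#49,test,4217.0
SES0 2,test,4186.3
GBK 034691,test,4183.5
GE35/1/2013A,test,4164.0
GBK-051500,test,4160.8
NAROSORG3,check,3714.1
NAROSORG2,check,3707.1
SESO1,check,3298.7
SESO3,check,3238.1
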