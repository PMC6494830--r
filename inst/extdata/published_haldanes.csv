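trait,control,hybrid_LBJ,hybrid_BFL
SLA,0.004,0.020,0.018
LeafLong,0.000,0.002,-0.002
LDMC,0.000,-0.007,-0.010
Succ,-0.006,-0.013,-0.008
Chloro,-0.008,0.005,-0.004
LWR,-0.002,-0.016,-0.007
WUE,-0.004,-0.011,-0.012
DaysToBud,0.001,0.028,0.005
SMT,-0.012,0.006,0.010
Longevity,0.000,0.006,0.002
DiskDiam,0.000,0.013,0.012
Volume,-0.001,0.014,0.010
HtLow,0.003,0.018,0.001
Bushy,0.004,0.005,0.003
RelBrDiam,0.005,-0.006,-0.001
GlandDens,0.002,0.011,0.008
HairDens,0.008,0.001,0.001
CNratio,0.008,-0.013,-0.002
SuckDam,-0.004,0.005,0.006
ChewDam,0.001,0.012,0.013
StemBorer,0.002,0.003,-0.001
WeevilDam,-0.002,0.003,0.012
MidgeDam,-0.005,-0.023,-0.017
ParaDam,-0.002,-0.011,0.008
HoleDam,-0.001,-0.016,-0.009
GSW,0.004,-0.008,-0.003
RecepDam,-0.003,-0.012,-0.001
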