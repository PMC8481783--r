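gene,degree,neighborhood_connectivity,subgraph_centrality
AAMP,16,19.6875,1066536
ABCA2,7,63.28571,2032188
ABCA6,12,40.08333,2517512
ACTA2,13,33,1265017
ADAMTS8,2,129,483438.2
AFP,6,59.5,1090336
AGA,2,129,483438.2
AGBL5,7,63.28571,2032188
ALDH1L2,2,129,483438.2
ANP32A,8,44.375,1095830
APIP,6,15,51842.77
ARFIP1,2,129,483438.2
ARHGEF7,7,63.28571,2032188
ARPC2,16,19.6875,1066536
ASB6,2,129,483438.2
ASPH,2,129,483438.2
ATF3,17,10,204496.1
ATF7IP,23,27.6,3275739
BAG3,11,31.36364,839991.3
BAIAP2,5,55,543055.9
BATF3,17,10,204496.1
BCL6,8,56.125,2101026
BRD4,7,63.28571,2032188
CCNI,2,129,483438.2
CCT5,2,129,483438.2
CD33,6,52.66667,697061.2
CDKN1B,13,33.84615,1540483
CEBPB,3,14.66667,8307.823
CHFR,8,51.57143,1029718
COL20A1,2,129,483438.2
CRTC2,8,59.5,1090336
CRYL1,2,129,483438.2
CYSLTR1,2,129,483438.2
DDB1,2,129,483438.2
DHX8,7,63.28571,2032188
DIS3,7,63.28571,2032188
DNMT3B,16,40.61538,2985855
DTX3,5,11.4,18321.32
DUSP6,2,129,483438.2
ECD,2,129,483438.2
EEF1B2,8,47,1208616
ELP5,2,129,483438.2
EPB42,2,129,483438.2
ERP27,7,44.85714,686034.2
FADS1,46,16.34091,4995617
FAM167A,13,6.615385,49473.38
FAM20B,2,129,483438.2
FCER1G,11,12.81818,141251.6
FGD4,5,58,592697.7
FGG,3,92.33333,551896.8
FLVCR2,2,129,483438.2
GBF1,22,27,3570302
GLI3,13,38.07692,2695724
GNA13,4,81.25,875946
GULP1,2,129,483438.2
HAUS4,2,129,483438.2
HEMGN,7,65.6,906075.6
HIC1,8,11.25,43296.84
IKBIP,2,129,483438.2
IKBKE,11,13,134489.2
IMP3,3,14.66667,8307.823
ING5,11,12.72727,194840.4
INPP4A,2,129,483438.2
INVS,7,63.28571,2032188
IQSEC1,5,58.4,625550.6
LIMCH1,12,41.08333,2669384
LLGL2,2,129,483438.2
LMAN2,24,22.45833,2625946
LOXL3,2,129,483438.2
LUZP1,7,63.28571,2032188
MAP3K8,6,52.5,811120
MBNL1,11,44.55556,1288207
MGAT5,12,34.45455,1180487
MMACHC,7,44,701632.3
MTHFD1L,13,40.76923,2703941
MTSS1,5,57.8,587272.6
MTUS1,2,129,483438.2
MVP,5,58.2,651412.9
NAGLU,5,60.4,617943.7
NOTCH1,34,21.58065,5186101
NPM1,10,10.6,76055.24
NQO1,9,11.22222,50685.27
NSUN6,15,24.4,920237.7
NUCKS1,13,34.30769,1624638
NUFIP2,5,55,543055.9
NUP35,2,129,483438.2
ODF2L,2,129,483438.2
PCBD2,15,21.4,1100177
PCSK5,3,87.66667,510939.4
PDCD11,10,47.7,2313937
PDLIM5,8,59.5,1090336
PDPR,2,129,483438.2
PIK3C2A,9,52,2218154
PIK3CB,2,129,483438.2
PLA2G7,4,71.75,599936.5
PLG,18,7.5,97555.15
PLXNA4,2,129,483438.2
POLB,2,129,483438.2
PPAN,3,86.33333,485964.5
PPFIA1,7,63.28571,2032188
PPP1CB,7,56.16667,954019.9
PTCD3,2,129,483438.2
PTEN,36,18.77778,5440125
PTPN22,36,16.76471,2848757
PTPN7,5,42.2,404444.5
PVR,12,11.91667,142451.7
RAB1B,6,10.66667,25252.28
RAN,13,28.30769,1013655
RNF13,4,9,5753.418
RPS24,2,129,483438.2
RPS6KC1,2,129,483438.2
RSRP1,2,6,1857.078
RUSC2,7,63.28571,2032188
SAMD10,3,14.66667,8307.823
SCAF8,11,45.72727,2543016
SEPHS1,2,129,483438.2
SESTD1,9,50.55556,2117183
SFXN1,2,129,483438.2
SGPP2,2,129,483438.2
SH3TC2,2,129,483438.2
SIN3B,7,63.28571,2032188
SLC12A6,8,56.625,2121072
SLC37A1,18,23.83333,1425904
SLC39A1,6,59.5,1090336
SLCO2A1,13,33.41667,1510348
SNX25,2,129,483438.2
SPATA6,2,129,483438.2
SPG11,7,63.28571,2032188
SPRY4,22,24.42857,2141129
ST14,2,129,483438.2
SUB1,7,34.42857,498913.4
SYNPO2,12,40.08333,2517512
TAF15,1,10,953.6951
TCF25,24,19.5,1637001
THUMPD3,2,129,483438.2
TMEM106B,7,8,16732.19
TMEM123,6,59.5,1090336
TMTC1,8,56.625,2121072
TNFRSF19,12,38.7,1291127
TPK1,6,67,945841.4
TPM4,2,129,483438.2
TPMT,10,28.8,663140.7
TRIM25,4,14.25,42289.27
TTPAL,2,129,483438.2
TXNL1,5,60.4,617943.7
UBA3,2,129,483438.2
UBASH3A,23,23.7619,2102919
USP37,2,129,483438.2
VPS37A,4,12.75,16391.32
XRCC1,2,129,483438.2
ZBTB37,2,129,483438.2
ZFPM2,17,32.47059,3141241
ZMIZ1,40,17.97368,4230617
ZMYND11,2,129,483438.2
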