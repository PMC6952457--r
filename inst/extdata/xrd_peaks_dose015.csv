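# dose_kGy=15
# source=XRD peak table, gamma-irradiated metoprolol tartrate
symbol,two_sin_theta,recip_d
B,0.18561,0.12048
C,0.20906,0.13587
D,0.24893,0.16175
E,0.26105,0.16945
F,0.27662,0.17950
G,0.29389,0.19144
H,0.31580,0.20493
I,0.33698,0.21896
J,0.35589,0.23112
K,0.37511,0.24310
L,0.38676,0.25244
M,0.40198,0.26093
N,0.40968,0.26598
O,0.41582,0.27042
P,0.43816,0.28458
Q,0.45330,0.29458
R,0.46333,0.30097
S,0.47588,0.30928
T,0.48401,0.31649
U,0.50752,0.32938
V,0.54540,0.35364
W,0.56970,0.37028
X,0.59142,0.38440
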