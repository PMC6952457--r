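# dose_kGy=0
# source=XRD peak table, gamma-irradiated metoprolol tartrate
symbol,two_sin_theta,recip_d
B,0.18561,0.12054
C,0.20906,0.13570
D,0.24893,0.16164
E,0.26105,0.16973
F,0.27662,0.17961
G,0.29389,0.19108
H,0.31580,0.20499
I,0.33698,0.21924
J,0.35589,0.23214
K,0.37511,0.24366
L,0.38676,0.25188
M,0.40198,0.26093
N,0.40968,0.26593
O,0.41582,0.27069
P,0.43816,0.28371
Q,0.45330,0.29491
R,0.46333,0.30003
S,0.47588,0.30814
T,0.48401,0.31434
U,0.50752,0.33010
V,0.54540,0.35314
W,0.56970,0.37001
X,0.59142,0.38454
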