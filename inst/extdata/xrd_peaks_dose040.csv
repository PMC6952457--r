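# dose_kGy=40
# source=XRD peak table, gamma-irradiated metoprolol tartrate
symbol,two_sin_theta,recip_d
B,0.18561,0.12127
C,0.20906,0.13655
D,0.24893,0.16265
E,0.26105,0.17052
F,0.27662,0.18040
G,0.29389,0.19212
H,0.31580,0.20549
I,0.33698,0.22047
J,0.35589,0.23224
K,0.37511,0.24382
L,0.38676,0.25199
M,0.40198,0.26166
N,0.40968,0.26654
O,0.41582,0.27096
P,0.43816,0.28552
Q,0.45330,0.29502
R,0.46333,0.30114
S,0.47588,0.30862
T,0.48401,0.31495
U,0.50752,0.32944
V,0.54540,0.35359
W,0.56970,0.37110
X,0.59142,0.38682
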