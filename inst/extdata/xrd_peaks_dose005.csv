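# dose_kGy=5
# source=XRD peak table, gamma-irradiated metoprolol tartrate
symbol,two_sin_theta,recip_d
B,0.18561,0.12071
C,0.20906,0.13559
D,0.24893,0.16227
E,0.26105,0.16990
F,0.27662,0.17972
G,0.29389,0.19178
H,0.31580,0.20460
I,0.33698,0.22013
J,0.35589,0.23185
K,0.37511,0.24321
L,0.38676,0.25221
M,0.40198,0.26082
N,0.40968,0.26587
O,0.41582,0.27020
P,0.43816,0.28431
Q,0.45330,0.29474
R,0.46333,0.30097
S,0.47588,0.30893
T,0.48401,0.31450
U,0.50752,0.32840
V,0.54540,0.35327
W,0.56970,0.37160
X,0.59142,0.38393
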