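# dose_kGy=20
# source=XRD peak table, gamma-irradiated metoprolol tartrate
symbol,two_sin_theta,recip_d
B,0.18561,0.11997
C,0.20906,0.13520
D,0.24893,0.16125
E,0.26105,0.16912
F,0.27662,0.17900
G,0.29389,0.19071
H,0.31580,0.20426
I,0.33698,0.21835
J,0.35589,0.23106
K,0.37511,0.24254
L,0.38676,0.25088
M,0.40198,0.26038
N,0.40968,0.26520
O,0.41582,0.26964
P,0.43816,0.28392
Q,0.45330,0.29386
R,0.46333,0.30047
S,0.47588,0.30807
T,0.48401,0.31457
U,0.50752,0.32879
V,0.54540,0.35403
W,0.56970,0.36997
X,0.59142,0.38405
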