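# dose_kGy=50
# source=XRD peak table, gamma-irradiated metoprolol tartrate
symbol,two_sin_theta,recip_d
B,0.18561,0.12054
C,0.20906,0.13546
D,0.24893,0.16192
E,0.26105,0.16939
F,0.27662,0.17954
G,0.29389,0.19150
H,0.31580,0.20493
I,0.33698,0.21952
J,0.35589,0.23106
K,0.37511,0.24337
L,0.38676,0.25183
M,0.40198,0.26088
N,0.40968,0.26576
O,0.41582,0.27047
P,0.43816,0.28469
Q,0.45330,0.29441
R,0.46333,0.30099
S,0.47588,0.30876
T,0.48401,0.31556
U,0.50752,0.32949
V,0.54540,0.35469
W,0.56970,0.37097
X,0.59142,0.38569
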