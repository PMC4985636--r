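A R N D C Q E G H I L K M F P S T W Y V
A -0.288
R -0.036 0.296
N 0 0 0
D 0.036 -0.296 0.000 0.296
C -0.504 -0.063 0.000 0.063 -0.882
Q 0 0 0 0 0 0
E 0.036 -0.296 0.000 0.296 0.063 0.000 0.296
G -0.180 -0.023 0.000 0.023 -0.315 0.000 0.023 -0.112
H -0.216 0.123 0.000 -0.123 -0.378 0.000 -0.123 -0.135 -0.087
I -0.540 -0.068 0.000 0.068 -0.945 0.000 0.068 -0.338 -0.405 -1.012
L -0.540 -0.068 0.000 0.068 -0.945 0.000 0.068 -0.338 -0.405 -1.012 -1.012
K 0.108 0.314 0.000 -0.314 0.189 0.000 -0.314 0.068 0.231 0.202 0.202 0.260
M -0.468 -0.059 0.000 0.059 -0.819 0.000 0.059 -0.293 -0.351 -0.878 -0.878 0.176 -0.761
F -0.576 -0.072 0.000 0.072 -1.008 0.000 0.072 -0.360 -0.432 -1.080 -1.080 0.216 -0.936 -1.152
P -0.108 -0.014 0.000 0.014 -0.189 0.000 0.014 -0.068 -0.081 -0.202 -0.202 0.040 -0.176 -0.216 -0.040
S -0.108 -0.014 0.000 0.014 -0.189 0.000 0.014 -0.068 -0.081 -0.202 -0.202 0.040 -0.176 -0.216 -0.040 -0.040
T -0.144 -0.018 0.000 0.018 -0.252 0.000 0.018 -0.090 -0.108 -0.270 -0.270 0.054 -0.234 -0.288 -0.054 -0.054 -0.072
W -0.540 -0.068 0.000 0.068 -0.945 0.000 0.068 -0.338 -0.405 -1.012 -1.012 0.202 -0.878 -1.080 -0.202 -0.202 -0.270 -1.012
Y -0.360 -0.045 0.000 0.045 -0.630 0.000 0.045 -0.225 -0.270 -0.675 -0.675 0.135 -0.585 -0.720 -0.135 -0.135 -0.180 -0.675 -0.450
V -0.468 -0.059 0.000 0.059 -0.819 0.000 0.059 -0.293 -0.351 -0.878 -0.878 0.176 -0.761 -0.936 -0.176 -0.176 -0.234 -0.878 -0.585 -0.761
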