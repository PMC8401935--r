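aa	frequency
A	0.089
R	0.055
N	0.040
D	0.054
C	0.011
E	0.061
Q	0.039
G	0.078
H	0.021
I	0.059
L	0.105
K	0.055
M	0.026
F	0.039
P	0.043
S	0.058
T	0.054
V	0.071
W	0.012
Y	0.030
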