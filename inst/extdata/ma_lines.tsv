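sample	treatment	mutations	callable_mb
A	indoor	0	126.4
E	indoor	0	125.7
I	indoor	0	126.0
J	indoor	0	126.4
N	indoor	0	125.9
B	outdoor-noUV	0	126.1
G	outdoor-noUV	1	126.3
K	outdoor-noUV	0	124.2
O	outdoor-noUV	0	125.9
P	outdoor-noUV	0	126.4
C	outdoor-UV	1	125.6
D	outdoor-UV	1	126.3
L	outdoor-UV	1	126.3
M	outdoor-UV	0	126.3
Q	outdoor-UV	0	126.0
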