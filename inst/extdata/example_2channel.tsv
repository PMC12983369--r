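#phase=liquid
#density_nm3=33.43
#provenance=
#channel elastic elastic 0 none
#channel ion ionisation 10.9 differential_table lorentz_a=8
5	0.050000000000000003	0
10	0.050000000000000003	0
40	0.050000000000000003	0.01
100	0.050000000000000003	0.02
1000	0.050000000000000003	0.01
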