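#concentration_nM=0.2
#frame_interval_s=0.5
#mode=binding_only
#seed=42
#substrate=D:R
#version=golden-1
time	donor	acceptor
0.000000	930.024615	47.877901
0.500000	1012.617841	-39.073077
1.000000	982.036145	22.509526
1.500000	1066.774936	76.314907
2.000000	1033.114903	-1.143510
2.500000	856.577043	34.306031
3.000000	961.462850	71.860032
3.500000	879.277834	76.520415
4.000000	491.003213	461.183811
4.500000	541.535362	392.172620
5.000000	479.448466	602.036060
5.500000	499.428995	445.305410
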