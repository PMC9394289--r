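channel	x	y	z
Fp1	-0.301328	0.859014	-0.071553
AF3	-0.344976	0.786540	0.217289
F3	-0.514319	0.543671	0.431897
F7	-0.719243	0.434786	-0.116900
FC5	-0.790407	0.190841	0.250384
FC1	-0.348673	0.266262	0.818784
C3	-0.669036	-0.119067	0.658798
T7	-0.861512	-0.163975	-0.095670
CP5	-0.814742	-0.476514	0.316808
CP1	-0.363528	-0.484102	0.934742
P3	-0.542607	-0.806508	0.572628
P7	-0.741471	-0.751896	-0.025458
PO3	-0.373747	-1.032377	0.380458
O1	-0.301089	-1.151080	0.090480
Oz	0.001101	-1.176087	0.150036
Pz	0.003324	-0.830330	0.845685
Fp2	0.305787	0.869033	-0.072474
AF4	0.365568	0.795638	0.224752
Fz	0.003196	0.598956	0.680336
F4	0.530619	0.555889	0.417791
F8	0.747703	0.454721	-0.122838
FC6	0.814148	0.204071	0.250159
FC2	0.356066	0.270630	0.806715
Cz	0.004104	-0.093838	1.026144
C4	0.687050	-0.111580	0.650834
T8	0.870917	-0.153755	-0.097144
CP6	0.852920	-0.471914	0.319439
CP2	0.392914	-0.481862	0.928396
P4	0.569830	-0.804178	0.578984
P8	0.747832	-0.747961	-0.026001
PO4	0.376513	-1.032338	0.372576
O2	0.305483	-1.148080	0.090081
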