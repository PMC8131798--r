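trait	quantity	female	male	difference
aggression	V_A	3.330	59.367	-56.036
aggression	V_CE	1.663	31.016	-29.353
aggression	V_PE	13.471	41.030	-27.559
aggression	V_R	0.723	110.382	-109.659
aggression	h2	0.088	0.212	-0.124
activity	V_A	0.006	0.071	-0.064
activity	V_CE	0.012	0.038	-0.026
activity	V_PE	0.027	0.170	-0.143
activity	V_R	0.116	0.035	0.081
activity	h2	0.039	0.222	-0.183
exploration	V_A	0.015	0.051	-0.036
exploration	V_CE	0.053	0.042	0.011
exploration	V_PE	0.144	0.203	-0.059
exploration	V_R	0.168	0.146	0.022
exploration	h2	0.039	0.111	-0.071
boldness	V_A	327.139	173.983	153.155
boldness	V_CE	379.028	208.236	170.792
boldness	V_PE	1326.757	1431.35	-104.593
boldness	V_R	2852.365	1100.852	1158.466
boldness	h2	0.064	0.059	0.005
aggression	CV_A	0.352	0.442	-0.090
aggression	CV_CE	0.239	0.301	-0.062
aggression	CV_PE	0.800	0.354	0.447
aggression	CV_R	0.171	0.642	-0.470
aggression	I_A	0.168	0.226	-0.058
activity	CV_A	0.161	0.707	-0.546
activity	CV_CE	0.232	0.206	0.026
activity	CV_PE	0.403	0.976	-0.573
activity	CV_R	0.868	0.592	0.277
activity	I_A	0.040	0.575	-0.535
exploration	CV_A	0.042	0.267	-0.225
exploration	CV_CE	0.061	0.078	-0.017
exploration	CV_PE	0.105	0.369	-0.264
exploration	CV_R	0.226	0.224	0.003
exploration	I_A	0.026	0.077	-0.051
boldness	CV_A	0.153	1.116	-0.963
boldness	CV_CE	0.221	0.326	-0.104
boldness	CV_PE	0.384	1.540	-1.157
boldness	CV_R	0.826	0.934	-0.108
boldness	I_A	0.234	0.174	0.061
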