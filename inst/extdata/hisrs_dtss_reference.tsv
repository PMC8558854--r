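residue	pathway	dtss	dtss_crystal
Asp13	TS0	0.57	0.30
Glu47	TS0	-2.25	-1.38
Glu83	TS0	-8.02	-9.46
Arg113	TS0	-5.43	-6.09
Glu131	TS0	-4.60	-5.53
Asp141	TS0	-2.97	-1.57
Arg259	TS0	5.26	8.44
Glu270	TS0	0.39	1.12
Arg287	TS0	3.26	1.77
Asp13	TS1	0.83	0.52
Glu47	TS1	0.09	-1.62
Glu83	TS1	-10.28	-18.18
Arg113	TS1	2.82	-6.21
Glu131	TS1	-6.54	-6.69
Asp141	TS1	-1.07	-1.47
Arg259	TS1	3.40	2.37
Glu270	TS1	-2.41	-0.64
Arg287	TS1	1.67	-1.13
Asp13	TS2	-0.68	0.51
Glu47	TS2	1.39	-0.15
Glu83	TS2	-4.38	-5.83
Arg113	TS2	0.63	5.38
Glu131	TS2	0.21	-0.56
Asp141	TS2	1.28	-0.45
Arg259	TS2	0.15	14.42
Glu270	TS2	-0.32	-4.43
Arg287	TS2	-1.96	0.03
Asp13	TS3	0.65	-0.10
Glu47	TS3	1.89	1.06
Glu83	TS3	-10.27	4.43
Arg113	TS3	1.48	-8.71
Glu131	TS3	-2.98	-1.80
Asp141	TS3	-1.01	-1.35
Arg259	TS3	7.03	0.18
Glu270	TS3	-4.72	-7.27
Arg287	TS3	1.35	-1.00
Asp13	TS4	0.09	0.04
Glu47	TS4	-0.45	0.92
Glu83	TS4	-2.58	2.38
Arg113	TS4	1.49	-8.11
Glu131	TS4	-1.14	-1.35
Asp141	TS4	-0.06	-1.18
Arg259	TS4	-0.42	-1.34
Glu270	TS4	0.48	-7.24
Arg287	TS4	0.21	-0.93
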