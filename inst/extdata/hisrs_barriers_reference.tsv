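pathway	reaction	b0	sum_dtss_printed	total_printed
TS0	His+ATP aminoacylation	37.28	-14.79	22.49
TS1	His-AMP+tRNA charging, variant 1	84.00	-11.48	72.52
TS2	His-AMP+tRNA charging, variant 2	103.41	-4.96	98.45
TS3	His-AMP+tRNA charging, variant 3	18.95	-6.58	12.37
TS4	His-AMP+tRNA charging, step 3->TS4	-0.04	-2.38	-2.42
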