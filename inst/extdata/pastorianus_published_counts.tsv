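metric	CBS1538	CBS1503	CBS1513	WS3470
total_orfs	7288	8714	9728	11265
assigned:Seub	5186	5075	5218	5024
assigned:Scer	1517	2936	3739	5312
ambiguous_equal_identity	9	10	9	7
subthreshold_identity	9	3	4	2
no_prediction	567	690	758	920
distinct_paralogs	2814	3056	3316	3652
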