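isolate_id	factor	level	timepoint_h	class
A2.48.2016	baseline	NA	24	NP
A2.48.2016	baseline	NA	48	WP
N9.25.2016	baseline	NA	24	NP
N9.25.2016	baseline	NA	48	NP
A1.6.2017	baseline	NA	24	SP
A1.6.2017	baseline	NA	48	WP
N10.27.2017	baseline	NA	24	NP
N10.27.2017	baseline	NA	48	NP
A4.16.2019	baseline	NA	24	WP
A4.16.2019	baseline	NA	48	MP
N9.1.2019	baseline	NA	24	MP
N9.1.2019	baseline	NA	48	MP
A4.26.2021	baseline	NA	24	MP
A4.26.2021	baseline	NA	48	WP
N10.1.2021	baseline	NA	24	NP
N10.1.2021	baseline	NA	48	WP
A1.14.2022	baseline	NA	24	SP
A1.14.2022	baseline	NA	48	SP
N10.55.2022	baseline	NA	24	WP
N10.55.2022	baseline	NA	48	MP
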