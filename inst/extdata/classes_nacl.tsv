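isolate_id	factor	level	timepoint_h	class
A2.48.2016	nacl	1	24	NP
A2.48.2016	nacl	1	48	NP
A2.48.2016	nacl	2	24	NP
A2.48.2016	nacl	2	48	NP
A2.48.2016	nacl	4	24	NP
A2.48.2016	nacl	4	48	NP
A2.48.2016	nacl	8	24	NP
A2.48.2016	nacl	8	48	NP
N9.25.2016	nacl	1	24	NP
N9.25.2016	nacl	1	48	NP
N9.25.2016	nacl	2	24	NP
N9.25.2016	nacl	2	48	NP
N9.25.2016	nacl	4	24	NP
N9.25.2016	nacl	4	48	NP
N9.25.2016	nacl	8	24	WP
N9.25.2016	nacl	8	48	WP
A1.6.2017	nacl	1	24	WP
A1.6.2017	nacl	1	48	MP
A1.6.2017	nacl	2	24	WP
A1.6.2017	nacl	2	48	WP
A1.6.2017	nacl	4	24	WP
A1.6.2017	nacl	4	48	WP
A1.6.2017	nacl	8	24	WP
A1.6.2017	nacl	8	48	SP
N10.27.2017	nacl	1	24	NP
N10.27.2017	nacl	1	48	NP
N10.27.2017	nacl	2	24	NP
N10.27.2017	nacl	2	48	NP
N10.27.2017	nacl	4	24	NP
N10.27.2017	nacl	4	48	NP
N10.27.2017	nacl	8	24	NP
N10.27.2017	nacl	8	48	NP
A4.16.2019	nacl	1	24	WP
A4.16.2019	nacl	1	48	WP
A4.16.2019	nacl	2	24	WP
A4.16.2019	nacl	2	48	NP
A4.16.2019	nacl	4	24	NP
A4.16.2019	nacl	4	48	NP
A4.16.2019	nacl	8	24	NP
A4.16.2019	nacl	8	48	NP
N9.1.2019	nacl	1	24	WP
N9.1.2019	nacl	1	48	WP
N9.1.2019	nacl	2	24	WP
N9.1.2019	nacl	2	48	WP
N9.1.2019	nacl	4	24	WP
N9.1.2019	nacl	4	48	WP
N9.1.2019	nacl	8	24	NP
N9.1.2019	nacl	8	48	WP
A4.26.2021	nacl	1	24	WP
A4.26.2021	nacl	1	48	WP
A4.26.2021	nacl	2	24	NP
A4.26.2021	nacl	2	48	NP
A4.26.2021	nacl	4	24	NP
A4.26.2021	nacl	4	48	NP
A4.26.2021	nacl	8	24	WP
A4.26.2021	nacl	8	48	SP
N10.1.2021	nacl	1	24	NP
N10.1.2021	nacl	1	48	WP
N10.1.2021	nacl	2	24	WP
N10.1.2021	nacl	2	48	WP
N10.1.2021	nacl	4	24	NP
N10.1.2021	nacl	4	48	NP
N10.1.2021	nacl	8	24	NP
N10.1.2021	nacl	8	48	WP
A1.14.2022	nacl	1	24	MP
A1.14.2022	nacl	1	48	SP
A1.14.2022	nacl	2	24	MP
A1.14.2022	nacl	2	48	MP
A1.14.2022	nacl	4	24	MP
A1.14.2022	nacl	4	48	SP
A1.14.2022	nacl	8	24	MP
A1.14.2022	nacl	8	48	MP
N10.55.2022	nacl	1	24	NP
N10.55.2022	nacl	1	48	MP
N10.55.2022	nacl	2	24	WP
N10.55.2022	nacl	2	48	WP
N10.55.2022	nacl	4	24	NP
N10.55.2022	nacl	4	48	WP
N10.55.2022	nacl	8	24	NP
N10.55.2022	nacl	8	48	MP
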