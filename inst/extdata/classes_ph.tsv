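isolate_id	factor	level	timepoint_h	class
A2.48.2016	ph	5	24	NP
A2.48.2016	ph	5	48	NP
A2.48.2016	ph	6	24	NP
A2.48.2016	ph	6	48	NP
A2.48.2016	ph	7	24	NP
A2.48.2016	ph	7	48	NP
A2.48.2016	ph	8	24	NP
A2.48.2016	ph	8	48	WP
A2.48.2016	ph	9	24	NP
A2.48.2016	ph	9	48	NP
N9.25.2016	ph	5	24	NP
N9.25.2016	ph	5	48	NP
N9.25.2016	ph	6	24	NP
N9.25.2016	ph	6	48	NP
N9.25.2016	ph	7	24	NP
N9.25.2016	ph	7	48	NP
N9.25.2016	ph	8	24	NP
N9.25.2016	ph	8	48	MP
N9.25.2016	ph	9	24	NP
N9.25.2016	ph	9	48	WP
A1.6.2017	ph	5	24	WP
A1.6.2017	ph	5	48	WP
A1.6.2017	ph	6	24	WP
A1.6.2017	ph	6	48	WP
A1.6.2017	ph	7	24	WP
A1.6.2017	ph	7	48	WP
A1.6.2017	ph	8	24	WP
A1.6.2017	ph	8	48	WP
A1.6.2017	ph	9	24	WP
A1.6.2017	ph	9	48	WP
N10.27.2017	ph	5	24	NP
N10.27.2017	ph	5	48	NP
N10.27.2017	ph	6	24	NP
N10.27.2017	ph	6	48	NP
N10.27.2017	ph	7	24	NP
N10.27.2017	ph	7	48	NP
N10.27.2017	ph	8	24	NP
N10.27.2017	ph	8	48	NP
N10.27.2017	ph	9	24	NP
N10.27.2017	ph	9	48	NP
A4.16.2019	ph	5	24	NP
A4.16.2019	ph	5	48	WP
A4.16.2019	ph	6	24	WP
A4.16.2019	ph	6	48	WP
A4.16.2019	ph	7	24	WP
A4.16.2019	ph	7	48	WP
A4.16.2019	ph	8	24	WP
A4.16.2019	ph	8	48	MP
A4.16.2019	ph	9	24	WP
A4.16.2019	ph	9	48	MP
N9.1.2019	ph	5	24	MP
N9.1.2019	ph	5	48	MP
N9.1.2019	ph	6	24	WP
N9.1.2019	ph	6	48	WP
N9.1.2019	ph	7	24	SP
N9.1.2019	ph	7	48	MP
N9.1.2019	ph	8	24	WP
N9.1.2019	ph	8	48	WP
N9.1.2019	ph	9	24	WP
N9.1.2019	ph	9	48	WP
A4.26.2021	ph	5	24	NP
A4.26.2021	ph	5	48	WP
A4.26.2021	ph	6	24	NP
A4.26.2021	ph	6	48	NP
A4.26.2021	ph	7	24	WP
A4.26.2021	ph	7	48	NP
A4.26.2021	ph	8	24	NP
A4.26.2021	ph	8	48	WP
A4.26.2021	ph	9	24	WP
A4.26.2021	ph	9	48	NP
N10.1.2021	ph	5	24	WP
N10.1.2021	ph	5	48	MP
N10.1.2021	ph	6	24	WP
N10.1.2021	ph	6	48	WP
N10.1.2021	ph	7	24	WP
N10.1.2021	ph	7	48	WP
N10.1.2021	ph	8	24	WP
N10.1.2021	ph	8	48	WP
N10.1.2021	ph	9	24	WP
N10.1.2021	ph	9	48	WP
A1.14.2022	ph	5	24	WP
A1.14.2022	ph	5	48	MP
A1.14.2022	ph	6	24	MP
A1.14.2022	ph	6	48	MP
A1.14.2022	ph	7	24	MP
A1.14.2022	ph	7	48	SP
A1.14.2022	ph	8	24	MP
A1.14.2022	ph	8	48	SP
A1.14.2022	ph	9	24	SP
A1.14.2022	ph	9	48	SP
N10.55.2022	ph	5	24	NP
N10.55.2022	ph	5	48	WP
N10.55.2022	ph	6	24	NP
N10.55.2022	ph	6	48	WP
N10.55.2022	ph	7	24	WP
N10.55.2022	ph	7	48	WP
N10.55.2022	ph	8	24	NP
N10.55.2022	ph	8	48	MP
N10.55.2022	ph	9	24	MP
N10.55.2022	ph	9	48	SP
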