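isolate_id	factor	level	timepoint_h	class
A2.48.2016	temperature	4	24	NP
A2.48.2016	temperature	4	48	NP
A2.48.2016	temperature	10	24	NP
A2.48.2016	temperature	10	48	NP
A2.48.2016	temperature	20	24	NP
A2.48.2016	temperature	20	48	NP
A2.48.2016	temperature	37	24	NP
A2.48.2016	temperature	37	48	WP
N9.25.2016	temperature	4	24	NP
N9.25.2016	temperature	4	48	WP
N9.25.2016	temperature	10	24	NP
N9.25.2016	temperature	10	48	NP
N9.25.2016	temperature	20	24	NP
N9.25.2016	temperature	20	48	NP
N9.25.2016	temperature	37	24	NP
N9.25.2016	temperature	37	48	NP
A1.6.2017	temperature	4	24	NP
A1.6.2017	temperature	4	48	NP
A1.6.2017	temperature	10	24	NP
A1.6.2017	temperature	10	48	NP
A1.6.2017	temperature	20	24	WP
A1.6.2017	temperature	20	48	WP
A1.6.2017	temperature	37	24	WP
A1.6.2017	temperature	37	48	WP
N10.27.2017	temperature	4	24	NP
N10.27.2017	temperature	4	48	NP
N10.27.2017	temperature	10	24	NP
N10.27.2017	temperature	10	48	NP
N10.27.2017	temperature	20	24	NP
N10.27.2017	temperature	20	48	NP
N10.27.2017	temperature	37	24	NP
N10.27.2017	temperature	37	48	NP
A4.16.2019	temperature	4	24	NP
A4.16.2019	temperature	4	48	NP
A4.16.2019	temperature	10	24	NP
A4.16.2019	temperature	10	48	NP
A4.16.2019	temperature	20	24	NP
A4.16.2019	temperature	20	48	WP
A4.16.2019	temperature	37	24	WP
A4.16.2019	temperature	37	48	MP
N9.1.2019	temperature	4	24	NP
N9.1.2019	temperature	4	48	NP
N9.1.2019	temperature	10	24	NP
N9.1.2019	temperature	10	48	NP
N9.1.2019	temperature	20	24	NP
N9.1.2019	temperature	20	48	WP
N9.1.2019	temperature	37	24	MP
N9.1.2019	temperature	37	48	MP
A4.26.2021	temperature	4	24	NP
A4.26.2021	temperature	4	48	NP
A4.26.2021	temperature	10	24	NP
A4.26.2021	temperature	10	48	NP
A4.26.2021	temperature	20	24	NP
A4.26.2021	temperature	20	48	NP
A4.26.2021	temperature	37	24	MP
A4.26.2021	temperature	37	48	WP
N10.1.2021	temperature	4	24	NP
N10.1.2021	temperature	4	48	NP
N10.1.2021	temperature	10	24	NP
N10.1.2021	temperature	10	48	WP
N10.1.2021	temperature	20	24	NP
N10.1.2021	temperature	20	48	WP
N10.1.2021	temperature	37	24	NP
N10.1.2021	temperature	37	48	WP
A1.14.2022	temperature	4	24	MP
A1.14.2022	temperature	4	48	MP
A1.14.2022	temperature	10	24	MP
A1.14.2022	temperature	10	48	MP
A1.14.2022	temperature	20	24	MP
A1.14.2022	temperature	20	48	WP
A1.14.2022	temperature	37	24	SP
A1.14.2022	temperature	37	48	SP
N10.55.2022	temperature	4	24	NP
N10.55.2022	temperature	4	48	NP
N10.55.2022	temperature	10	24	NP
N10.55.2022	temperature	10	48	NP
N10.55.2022	temperature	20	24	NP
N10.55.2022	temperature	20	48	WP
N10.55.2022	temperature	37	24	WP
N10.55.2022	temperature	37	48	MP
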