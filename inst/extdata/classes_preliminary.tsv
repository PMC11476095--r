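isolate_id	factor	level	timepoint_h	class
A1.40.2016	baseline	NA	24	NP
A1.40.2016	baseline	NA	48	WP
A2.48.2016	baseline	NA	24	NP
A2.48.2016	baseline	NA	48	WP
A3.34.2016	baseline	NA	24	NP
A3.34.2016	baseline	NA	48	WP
A4.19.2016	baseline	NA	24	NP
A4.19.2016	baseline	NA	48	NP
A5.17.2016	baseline	NA	24	NP
A5.17.2016	baseline	NA	48	NP
N9.25.2016	baseline	NA	24	NP
N9.25.2016	baseline	NA	48	WP
N10.46.2016	baseline	NA	24	WP
N10.46.2016	baseline	NA	48	NP
A1.6.2017	baseline	NA	24	SP
A1.6.2017	baseline	NA	48	WP
A2.17.2017	baseline	NA	24	NP
A2.17.2017	baseline	NA	48	NP
A3.9.2017	baseline	NA	24	WP
A3.9.2017	baseline	NA	48	WP
A4.6.2017	baseline	NA	24	NP
A4.6.2017	baseline	NA	48	NP
A5.18.2017	baseline	NA	24	MP
A5.18.2017	baseline	NA	48	WP
N9.1.2017	baseline	NA	24	NP
N9.1.2017	baseline	NA	48	NP
N10.27.2017	baseline	NA	24	NP
N10.27.2017	baseline	NA	48	NP
A1.9.2019	baseline	NA	24	WP
A1.9.2019	baseline	NA	48	MP
A2.20.2019	baseline	NA	24	NP
A2.20.2019	baseline	NA	48	WP
A3.2.2019	baseline	NA	24	NP
A3.2.2019	baseline	NA	48	WP
A4.16.2019	baseline	NA	24	WP
A4.16.2019	baseline	NA	48	MP
N9.1.2019	baseline	NA	24	MP
N9.1.2019	baseline	NA	48	MP
N10.14.2019	baseline	NA	24	NP
N10.14.2019	baseline	NA	48	MP
A1.2.2021	baseline	NA	24	MP
A1.2.2021	baseline	NA	48	WP
A1.24.2021	baseline	NA	24	MP
A1.24.2021	baseline	NA	48	WP
A1.45.2021	baseline	NA	24	NP
A1.45.2021	baseline	NA	48	WP
A1.59.2021	baseline	NA	24	NP
A1.59.2021	baseline	NA	48	WP
A2.3.2021	baseline	NA	24	NP
A2.3.2021	baseline	NA	48	NP
A2.17.2021	baseline	NA	24	WP
A2.17.2021	baseline	NA	48	MP
A2.32.2021	baseline	NA	24	NP
A2.32.2021	baseline	NA	48	NP
A2.58.2021	baseline	NA	24	NP
A2.58.2021	baseline	NA	48	NP
A3.4.2021	baseline	NA	24	NP
A3.4.2021	baseline	NA	48	WP
A3.9.2021	baseline	NA	24	WP
A3.9.2021	baseline	NA	48	NP
A3.16.2021	baseline	NA	24	NP
A3.16.2021	baseline	NA	48	WP
A3.19.2021	baseline	NA	24	NP
A3.19.2021	baseline	NA	48	MP
A3.26.2021	baseline	NA	24	NP
A3.26.2021	baseline	NA	48	WP
A3.39.2021	baseline	NA	24	NP
A3.39.2021	baseline	NA	48	MP
A3.45.2021	baseline	NA	24	NP
A3.45.2021	baseline	NA	48	WP
A4.7.2021	baseline	NA	24	NP
A4.7.2021	baseline	NA	48	NP
A4.11.2021	baseline	NA	24	WP
A4.11.2021	baseline	NA	48	NP
A4.21.2021	baseline	NA	24	NP
A4.21.2021	baseline	NA	48	NP
A4.26.2021	baseline	NA	24	MP
A4.26.2021	baseline	NA	48	WP
A4.41.2021	baseline	NA	24	WP
A4.41.2021	baseline	NA	48	WP
N9.21.2021	baseline	NA	24	NP
N9.21.2021	baseline	NA	48	WP
N9.46.2021	baseline	NA	24	NP
N9.46.2021	baseline	NA	48	NP
N9.58.2021	baseline	NA	24	NP
N9.58.2021	baseline	NA	48	NP
N10.1.2021	baseline	NA	24	NP
N10.1.2021	baseline	NA	48	WP
N10.21.2021	baseline	NA	24	MP
N10.21.2021	baseline	NA	48	NP
N10.45.2021	baseline	NA	24	NP
N10.45.2021	baseline	NA	48	MP
N10.47.2021	baseline	NA	24	WP
N10.47.2021	baseline	NA	48	MP
N10.49.2021	baseline	NA	24	WP
N10.49.2021	baseline	NA	48	WP
A1.14.2022	baseline	NA	24	SP
A1.14.2022	baseline	NA	48	SP
A1.54.2022	baseline	NA	24	WP
A1.54.2022	baseline	NA	48	MP
A2.1.2022	baseline	NA	24	NP
A2.1.2022	baseline	NA	48	NP
A2.23.2022	baseline	NA	24	NP
A2.23.2022	baseline	NA	48	NP
A2.34.2022	baseline	NA	24	NP
A2.34.2022	baseline	NA	48	WP
A2.38.2022	baseline	NA	24	WP
A2.38.2022	baseline	NA	48	WP
A3.14.2022	baseline	NA	24	WP
A3.14.2022	baseline	NA	48	NP
A3.38.2022	baseline	NA	24	MP
A3.38.2022	baseline	NA	48	WP
A3.47.2022	baseline	NA	24	NP
A3.47.2022	baseline	NA	48	NP
A3.49.2022	baseline	NA	24	NP
A3.49.2022	baseline	NA	48	WP
A3.57.2022	baseline	NA	24	NP
A3.57.2022	baseline	NA	48	WP
A4.5.2022	baseline	NA	24	NP
A4.5.2022	baseline	NA	48	MP
A4.11.2022	baseline	NA	24	NP
A4.11.2022	baseline	NA	48	WP
A4.12.2022	baseline	NA	24	WP
A4.12.2022	baseline	NA	48	MP
A4.20.2022	baseline	NA	24	WP
A4.20.2022	baseline	NA	48	MP
A4.30.2022	baseline	NA	24	WP
A4.30.2022	baseline	NA	48	MP
A4.43.2022	baseline	NA	24	NP
A4.43.2022	baseline	NA	48	WP
A4.54.2022	baseline	NA	24	NP
A4.54.2022	baseline	NA	48	WP
A4.59.2022	baseline	NA	24	WP
A4.59.2022	baseline	NA	48	WP
N9.1.2022	baseline	NA	24	WP
N9.1.2022	baseline	NA	48	WP
N9.23.2022	baseline	NA	24	WP
N9.23.2022	baseline	NA	48	MP
N9.58.2022	baseline	NA	24	NP
N9.58.2022	baseline	NA	48	WP
N10.18.2022	baseline	NA	24	WP
N10.18.2022	baseline	NA	48	MP
N10.55.2022	baseline	NA	24	WP
N10.55.2022	baseline	NA	48	MP
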