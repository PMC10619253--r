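cohort	item	n	pct
GNHS	total	1920	NA
GNHS	women	1288	67.1
GNHS	t2d	268	14.0
GNHS	NE2	37	1.9
GNHS	E1	34	1.8
GNHS	E2	15	0.8
GNHS	E3	5	0.3
GNHS	E4	341	17.8
GNHS	E5	425	22.1
GNHS	E6	670	34.9
GNHS	E7	261	13.6
GNHS	E8	91	4.7
GNHS	NE1	41	2.1
GGMP	total	6560	NA
GGMP	women	3614	55.1
GGMP	t2d	553	8.4
GGMP	NE2	622	9.5
GGMP	E1	144	2.2
GGMP	E2	111	1.7
GGMP	E3	111	1.7
GGMP	E4	512	7.8
GGMP	E5	502	7.7
GGMP	E6	822	12.5
GGMP	E7	380	5.8
GGMP	E8	430	6.6
GGMP	NE1	2926	44.6
CHNS	total	3033	NA
CHNS	women	1554	51.2
CHNS	t2d	368	12.2
CHNS	NE2	303	10.0
CHNS	E1	69	2.3
CHNS	E2	58	1.9
CHNS	E3	48	1.6
CHNS	E4	259	8.5
CHNS	E5	300	9.9
CHNS	E6	340	11.2
CHNS	E7	137	4.5
CHNS	E8	109	3.6
CHNS	NE1	1410	46.5
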