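patient_id	location	nice	n_lesions	size
P01	Cecum	1	1	<5 mm
P02	Cecum	1	1	<5 mm
P03	Cecum	1	1	<5 mm
P04	Ascending colon	1	1	<5 mm
P05	Ascending colon	1	1	<5 mm
P06	Ascending colon	1	1	<5 mm
P07	Ascending colon	1	1	<5 mm
P08	Ascending colon	1	1	<5 mm
P09	Ascending colon	1	1	<5 mm
P10	Ascending colon	1	1	<5 mm
P11	Ascending colon	2	1	<5 mm
P12	Ascending colon	2	1	6-9 mm
P13	Ascending colon	2	1	6-9 mm
P14	Transverse colon	2	1	6-9 mm
P15	Transverse colon	2	1	6-9 mm
P16	Transverse colon	2	1	6-9 mm
P17	Transverse colon	2	1	6-9 mm
P18	Descending colon	2	1	6-9 mm
P19	Descending colon	2	1	6-9 mm
P20	Descending colon	2	1	6-9 mm
P21	Descending colon	2	1	6-9 mm
P22	Descending colon	2	1	6-9 mm
P23	Sigmoid colon	2	1	6-9 mm
P24	Sigmoid colon	2	1	6-9 mm
P25	Sigmoid colon	2	1	6-9 mm
P26	Sigmoid colon	2	1	6-9 mm
P27	Sigmoid colon	2	1	6-9 mm
P28	Sigmoid colon	2	1	10-14 mm
P29	Sigmoid colon	2	1	10-14 mm
P30	Sigmoid colon	2	1	10-14 mm
P31	Sigmoid colon	2	1	10-14 mm
P32	Sigmoid colon	2	1	10-14 mm
P33	Sigmoid colon	2	1	10-14 mm
P34	Sigmoid colon	2	1	10-14 mm
P35	Sigmoid colon	2	2	10-14 mm
P36	Sigmoid colon	2	2	10-14 mm
P37	Sigmoid colon	2	2	10-14 mm
P38	Sigmoid colon	2	2	15-19 mm
P39	Sigmoid colon	2	2	15-19 mm
P40	Sigmoid colon	2	2	15-19 mm
P41	Sigmoid colon	2	2	15-19 mm
P42	Sigmoid colon	2	2	15-19 mm
P43	Sigmoid colon	2	2	15-19 mm
P44	Rectum	2	2	15-19 mm
P45	Rectum	2	2	>20 mm
P46	Rectum	2	2	>20 mm
P47	Rectum	3	2	>20 mm
P48	Rectum	3	2	>20 mm
P49	Rectum	3	3	>20 mm
P50	Rectum	3	5	>20 mm
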