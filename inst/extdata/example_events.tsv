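onset	duration	trial_type	response_time
2	2	S5	n/a
4	2	go	341.9
8	2	S1	n/a
10	2	go	301.5
14	2	S3	n/a
16	2	go	208.7
20	2	S3	n/a
22	2	go	309.1
26	2	S2	n/a
28	2	go	427.5
32	2	S2	n/a
34	2	go	329.8
38	2	S4	n/a
40	2	go	262.2
44	2	S5	n/a
46	2	go	278.0
50	2	S4	n/a
52	2	go	280.5
56	2	S1	n/a
58	2	go	277.5
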