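table	source	log_b10	pa	tp	tn	fp	fn
single_recording_kfold	PHEN	10.17	0.61	178	651	170	340
single_recording_kfold	STRU	31.19	0.66	112	776	45	406
single_recording_kfold	MOT	-1.73	0.60	71	733	88	447
single_recording_kfold	REHO	28.10	0.66	158	729	92	360
single_recording_kfold	SMR0	3.95	0.61	90	737	84	428
single_recording_kfold	SMR1	-0.66	0.60	78	731	90	440
single_recording_kfold	SMR2	2.98	0.61	77	750	71	441
single_recording_kfold	SMR3	1.72	0.61	80	741	80	438
single_recording_kfold	SMR4	7.40	0.62	86	753	68	432
single_recording_kfold	SMR5	0.46	0.60	77	739	82	441
single_recording_kfold	SMR6	1.94	0.61	89	730	91	429
single_recording_kfold	SMR7	4.50	0.61	110	713	108	408
single_recording_kfold	SMR8	1.68	0.60	94	722	99	424
single_recording_kfold	SMR9	3.95	0.61	90	737	84	428
single_recording_kfold	BAEF	12.21	0.63	134	713	108	384
single_subject_kfold	PHEN	-2.37	0.56	101	415	149	255
single_subject_kfold	STRU	-0.97	0.61	42	520	44	314
single_subject_kfold	MOT	-2.32	0.60	43	509	55	313
single_subject_kfold	REHO	17.05	0.65	101	504	60	255
single_subject_kfold	SMR0	1.64	0.61	68	497	67	288
single_subject_kfold	SMR1	0.12	0.60	65	494	70	291
single_subject_kfold	SMR2	-0.02	0.61	55	507	57	301
single_subject_kfold	SMR3	-1.75	0.60	49	505	59	307
single_subject_kfold	SMR4	-0.58	0.60	50	511	53	306
single_subject_kfold	SMR5	-0.65	0.60	49	512	52	307
single_subject_kfold	SMR6	-0.63	0.60	57	501	63	299
single_subject_kfold	SMR7	-2.32	0.59	57	487	77	299
single_subject_kfold	SMR8	5.21	0.62	73	503	61	283
single_subject_kfold	SMR9	1.64	0.61	68	497	67	288
single_subject_kfold	BAEF	10.37	0.64	99	489	75	257
single_leave_one_site_out	PHEN	-1.37	0.53	77	416	148	279
single_leave_one_site_out	STRU	-0.87	0.56	29	494	70	327
single_leave_one_site_out	MOT	1.41	0.55	29	482	82	327
single_leave_one_site_out	REHO	-1.45	0.56	41	477	87	315
single_leave_one_site_out	SMR0	-1.97	0.56	42	480	84	314
single_leave_one_site_out	SMR1	-0.56	0.56	28	494	70	328
single_leave_one_site_out	SMR2	-2.88	0.58	42	495	69	314
single_leave_one_site_out	SMR3	-2.22	0.57	32	499	65	324
single_leave_one_site_out	SMR4	-1.86	0.57	36	489	75	320
single_leave_one_site_out	SMR5	-2.63	0.58	33	502	62	323
single_leave_one_site_out	SMR6	-2.60	0.57	42	488	76	314
single_leave_one_site_out	SMR7	-2.80	0.57	48	484	80	308
single_leave_one_site_out	SMR8	-2.42	0.57	46	479	85	310
single_leave_one_site_out	SMR9	-2.18	0.56	44	479	85	312
single_leave_one_site_out	BAEF	3.10	0.50	82	376	188	274
multi_recording_kfold	TOP4	147.78	0.80	351	719	102	167
multi_recording_kfold	ALL	72.04	0.72	245	722	99	273
multi_subject_kfold	TOP4	24.53	0.67	174	442	122	182
multi_subject_kfold	ALL	22.57	0.67	140	476	88	216
multi_leave_one_site_out	TOP4	0.04	0.50	94	375	189	262
multi_leave_one_site_out	ALL	-1.75	0.57	97	432	132	259
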