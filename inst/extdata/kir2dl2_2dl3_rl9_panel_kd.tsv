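peptide	kd_2dl2	sd_2dl2	kd_2dl3	sd_2dl3	n	p_reported	q_reported
WT	4.9	0.3	4.2	0.3	2	0.31	0.39
P7E	NA	NA	NA	NA	2	NA	NA
P7F	14.4	0.5	12.4	1.6	2	0.23	0.37
P7G	27.9	2.1	21.0	1.6	2	0.07	0.27
P7A	27.7	3.3	20.6	0.7	2	0.10	0.27
P7N	29.7	5.7	21.5	1.5	2	0.19	0.35
P7R	17.6	0.9	14.4	3.0	2	0.28	0.39
P8E	NA	NA	NA	NA	2	NA	NA
P8F	6.5	0.4	5.1	0.4	2	0.07	0.27
P8G	18.9	0.7	11.7	0.8	2	0.01	0.12
P8V	7.5	1.0	5.6	0.6	2	0.15	0.33
P8N	20.0	5.8	19.9	2.0	2	0.99	0.99
P8R	23.9	1.5	22.8	1.5	2	0.54	0.60
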