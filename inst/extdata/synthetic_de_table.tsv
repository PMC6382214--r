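probe	gene	p_24h	fc_24h	p_48h	fc_48h	control_log2_24h	control_log2_48h	mfe	prediction_consensus
ps001	GENE01	0.002	-2.8	0.010	-1.9	11.2	11.0	-22.1	8
ps002	GENE02	0.004	-2.5	0.030	-1.4	12.0	11.8	-19.4	6
ps003	GENE03	0.001	-2.3	0.020	-1.6	10.8	10.5	-17.8	7
ps004	GENE04	0.010	-2.1	0.040	-1.3	11.5	11.2	-16.9	9
ps005	GENE04	0.012	-2.0	0.045	-1.2	11.4	11.1	-16.9	9
ps006	GENE05	0.006	-1.9	0.015	-1.5	12.3	12.0	-21.0	6
ps007	GENE06	0.020	-1.8	0.035	-1.3	10.6	10.4	-18.2	10
ps008	GENE07	0.015	-1.7	0.025	-1.4	11.0	10.9	-15.6	7
ps009	GENE08	0.030	-1.6	0.048	-1.2	10.9	10.2	-20.3	12
ps010	GENE09	0.040	-1.5	0.044	-1.3	10.4	10.1	-15.2	6
ps011	GENE10	0.003	-2.6	0.400	-1.1	11.8	11.5	-23.0	8
ps012	GENE11	0.250	-1.9	0.010	-1.8	11.1	10.8	-19.9	7
ps013	GENE12	0.008	-2.2	0.030	-1.5	9.4	9.1	-18.5	5
ps014	GENE13	0.018	-1.9	0.020	-1.4	11.6	11.3	-13.8	11
ps015	GENE14	0.005	-2.4	0.015	-1.7	12.1	11.9	-14.2	4
ps016	GENE15	0.045	-1.6	0.300	-1.0	10.7	10.3	-17.3	NA
ps017	GENE16	0.002	1.9	0.010	1.5	11.3	11.4	-16.1	3
ps018	GENE17	0.060	-1.8	0.070	-1.4	11.9	11.6	-18.8	6
ps019	GENE18	0.025	-1.4	0.035	-1.2	9.8	9.6	-21.5	9
ps020	GENE19	0.001	-3.1	0.005	-2.2	9.8	8.9	-24.0	12
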