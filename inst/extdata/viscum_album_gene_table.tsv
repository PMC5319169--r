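gene	length_lir_nt	length_va_nt	length_vs_nt	pct_id_va_lir	pct_id_va_vs	dN	dS	omega
atp9	225	225	219	82.7	91.8	0.044	0.216	0.20
rps12	375	417	411	68.0	98.3	0.010	0.048	0.21
atp1	1527	1536	1536	73.1	99.8	0.001	0.004	0.22
cox1	1572	1602	1602	81.4	99.6	0.003	0.010	0.24
cox3	795	738	795	75.1	99.2	0.006	0.017	0.33
rps3	1554	1455	1518	50.4	97.6	0.018	0.044	0.41
ccmFc	1326	1305	1218	51.1	96.3	0.029	0.067	0.43
sdh3	282	222	186	54.8	97.3	0.022	0.047	0.47
atp6	720	915	915	75.5	99.0	0.008	0.016	0.51
ccmFn	1683	1776	1467	51.8	96.7	0.029	0.051	0.56
mttB	720	765	789	63.2	96.9	0.029	0.042	0.68
atp4	558	471	474	41.5	98.5	0.014	0.020	0.69
cob	1179	1209	1221	74.4	99.3	0.006	0.008	0.73
rps4	1035	1005	1224	51.8	96.1	0.037	0.050	0.75
rpl16	432	378	378	63.2	98.4	0.015	0.019	0.79
ccmC	699	654	654	65.9	99.5	0.004	0.005	0.84
atp8	474	492	483	56.0	98.3	0.016	0.019	0.85
cox2	762	750	750	76.3	99.6	0.005	0.000	NA
rps10	357	273	273	59.4	99.6	0.006	0.000	NA
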