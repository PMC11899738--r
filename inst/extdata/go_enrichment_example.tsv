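term	total_genes	observed	expected	fold_enrichment	bonferroni_p
GO:0010438	7	4	0.13	29.68	1.25e-2
GO:0010106	8	4	0.15	25.97	2.46e-2
GO:0080136	13	6	0.25	23.97	2.08e-4
GO:0009627	67	13	1.29	10.08	1.17e-6
GO:0036294	239	28	4.6	6.08	7.25e-11
GO:0045087	183	16	3.52	4.54	1.57e-3
GO:0000302	166	14	3.2	4.38	1.21e-2
GO:0042742	389	31	7.49	4.14	8.96e-8
GO:0080134	474	31	9.13	3.4	1.13e-5
GO:0009605	1410	83	27.15	3.06	2.07e-16
GO:0006970	579	34	11.15	3.05	3.01e-5
GO:0009651	482	28	9.28	3.02	7.52e-4
GO:0070887	1133	62	21.81	2.84	4.19e-10
GO:0042221	2743	134	52.81	2.54	4.21e-21
GO:0009628	2257	93	43.46	2.14	5.86e-9
GO:0009059	2351	13	45.27	0.29	2.69e-5
GO:0010467	1924	8	37.04	0.22	2.01e-5
GO:0090304	1870	7	36	0.19	7.49e-6
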