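# GO biological-process over-representation of the signature genes, as
# printed: upper-tail hypergeometric p, 2x2 odds ratio, expected overlap
# (2 decimals), overlap count and term size. Selection and universe sizes
# are not printed; reconstruct_table_params() recovers them.
term_id	pvalue	odds_ratio	expected	count	size	term_name
GO:0006955	1.4E-12	31.69	1.04	13	620	Immune response
GO:0002376	4.6E-12	26.94	1.47	14	874	Immune system process
GO:0002504	1.8E-08	208.89	0.03	4	18	Antigen processing and presentation of peptide or polysaccharide antigen via MHC class II
GO:0019882	3.5E-08	73.05	0.10	5	58	Antigen processing and presentation
GO:0050896	3.6E-06	8.20	4.13	14	2454	Response to stimulus
GO:0002828	4.0E-05	327.34	0.01	2	6	Regulation of T-helper 2 type immune response
GO:0002682	6.7E-05	14.53	0.45	5	267	Regulation of immune system process
GO:0042092	1.2E-04	163.62	0.02	2	10	T-helper 2 type immune response
GO:0006954	1.4E-04	12.44	0.52	5	310	Inflammatory response
GO:0030217	1.5E-04	34.98	0.10	3	62	T cell differentiation
GO:0045058	1.8E-04	130.87	0.02	2	12	T cell selection
GO:0006952	2.2E-04	8.75	0.93	6	550	Defense response
GO:0045582	3.2E-04	93.45	0.03	2	16	Positive regulation of T cell differentiation
GO:0045621	4.1E-04	81.76	0.03	2	18	Positive regulation of lymphocyte differentiation
GO:0002460	4.7E-04	23.13	0.16	3	92	Adaptive immune response based on somatic recombination of immune receptors built from immunoglobulin superfamily domains
GO:0030098	4.7E-04	23.13	0.16	3	92	Lymphocyte differentiation
GO:0002250	4.9E-04	22.88	0.16	3	93	Adaptive immune response
GO:0044419	5.8E-04	12.38	0.40	4	236	Interspecies interaction between organisms
GO:0009611	7.2E-04	8.52	0.75	5	445	Response to wounding
GO:0002694	8.8E-04	18.52	0.19	3	114	Regulation of leukocyte activation
GO:0050865	1.0E-03	17.56	0.20	3	120	Regulation of cell activation
GO:0045580	1.1E-03	46.67	0.05	2	30	Regulation of T cell differentiation
GO:0051704	1.2E-03	7.57	0.84	5	498	Multi-organism process
GO:0042110	1.4E-03	15.54	0.23	3	135	T cell activation
GO:0050776	1.7E-03	14.54	0.24	3	144	Regulation of immune response
GO:0002822	1.8E-03	36.28	0.06	2	38	Regulation of adaptive immune response based on somatic recombination of immune receptors built from immunoglobulin superfamily domains
GO:0045619	1.8E-03	36.28	0.06	2	38	Regulation of lymphocyte differentiation
GO:0002819	1.9E-03	35.29	0.07	2	39	Regulation of adaptive immune response
GO:0002521	1.9E-03	13.94	0.25	3	150	Leukocyte differentiation
GO:0002684	1.9E-03	13.94	0.25	3	150	Positive regulation of immune system process
GO:0006935	2.1E-03	13.57	0.26	3	154	Chemotaxis
GO:0042330	2.1E-03	13.57	0.26	3	154	Taxis
GO:0007267	2.3E-03	6.50	0.97	5	576	Cell-cell signaling
GO:0050870	3.5E-03	25.58	0.09	2	53	Positive regulation of T cell activation
GO:0046649	4.2E-03	10.52	0.33	3	197	Lymphocyte activation
GO:0051251	5.0E-03	21.37	0.11	2	63	Positive regulation of lymphocyte activation
GO:0007626	5.5E-03	9.52	0.37	3	217	Locomotory behavior
GO:0009605	5.6E-03	5.20	1.20	5	710	Response to external stimulus
GO:0030097	5.6E-03	9.43	0.37	3	219	Hemopoiesis
GO:0002696	6.3E-03	18.88	0.12	2	71	Positive regulation of leukocyte activation
GO:0050867	6.6E-03	18.34	0.12	2	73	Positive regulation of cell activation
GO:0045321	6.8E-03	8.77	0.40	3	235	Leukocyte activation
GO:0048534	7.1E-03	8.66	0.40	3	238	Hemopoietic or lymphoid organ development
GO:0048583	7.2E-03	8.62	0.40	3	239	Regulation of response to stimulus
GO:0050863	8.1E-03	16.47	0.14	2	81	Regulation of T cell activation
GO:0002520	8.4E-03	8.13	0.43	3	253	Immune system development
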