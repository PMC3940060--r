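pathway_name	background_count	overlap_count	percent_printed	p_value_printed	fdr_printed
Citrate cycle (TCA cycle)	30	5	16.7	0.000401	0.0037
Ribosome	136	21	15.7	7.52E-13	6.21E-11
Parkinson's disease	131	20	15.4	3.87E-12	2.02E-10
Aldosterone-regulated sodium reabsorption	39	6	15.4	0.000165	0.00199
Type II diabetes mellitus	48	7	14.6	6.66E-05	0.00105
Oxidative phosphorylation	133	19	14.4	4.55E-11	1.78E-09
mTOR signaling pathway	60	8	13.3	3.89E-05	0.000764
Huntington's disease	183	24	13.2	7.92E-13	6.21E-11
Progesterone-mediated oocyte maturation	86	11	12.8	2.08E-06	4.66E-05
Insulin signaling pathway	142	17	12.1	8.01E-09	2.10E-07
Ovarian steroidogenesis	51	6	11.8	0.000735	0.00525
Long-term depression	60	7	11.7	0.000281	0.00294
Amyotrophic lateral sclerosis (ALS)	53	6	11.3	0.000905	0.00592
Alzheimer's disease	170	19	11.2	3.36E-09	1.05E-07
Cardiac muscle contraction	77	8	10.5	0.000214	0.0024
Gap junction	89	9	10.1	0.000118	0.00155
Prostate cancer	89	9	10.1	0.000118	0.00155
Estrogen signaling pathway	100	10	10.0	5.44E-05	0.00095
Colorectal cancer	62	6	9.7	0.00206	0.0101
Glioma	65	6	9.2	0.00263	0.012
Pancreatic cancer	66	6	9.1	0.00284	0.0124
GABAergic synapse	90	8	9.0	0.000631	0.00524
Adipocytokine signaling pathway	71	6	8.6	0.00382	0.0154
PPAR signaling pathway	71	6	8.5	0.0041	0.0157
Circadian entrainment	97	8	8.3	0.00104	0.00629
Prolactin signaling pathway	72	6	8.3	0.0044	0.0157
Chronic myeloid leukemia	73	6	8.2	0.0047	0.0164
Cholinergic synapse	113	9	8.0	0.000667	0.00524
Oocyte meiosis	112	9	8.0	0.000667	0.00524
Serotonergic synapse	114	9	8.0	0.000711	0.00525
Insulin secretion	87	7	8.0	0.00261	0.012
Gastric acid secretion	75	6	8.0	0.00537	0.0183
HIF-1 signaling pathway	106	8	7.5	0.00198	0.01
Peroxisome	81	6	7.5	0.00734	0.0226
TGF-beta signaling pathway	80	6	7.5	0.00734	0.0226
Cell cycle	124	9	7.3	0.00138	0.00803
Dopaminergic synapse	131	9	6.9	0.00192	0.01
Glutamatergic synapse	118	8	6.8	0.00366	0.0151
Proteoglycans in cancer	225	14	6.2	0.000348	0.00342
RNA transport	165	10	6.1	0.00268	0.012
Hepatitis B	147	9	6.1	0.00439	0.0157
HTLV-I infection	267	14	5.3	0.00161	0.00869
Chemokine signaling pathway	192	10	5.3	0.00732	0.0226
PI3K-Akt signaling pathway	347	16	4.6	0.00312	0.0133
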