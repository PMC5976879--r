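species	total_strains	n_with_bsh	pct_with_bsh	n_with_1	n_with_2	n_with_3
Lactobacillus acidophilus	16	15	93.75	0	15	0
Lactobacillus agilis	2	2	100.00	1	1	0
Lactobacillus amylovorus	6	6	100.00	5	1	0
Lactobacillus animalis	3	3	100.00	3	0	0
Lactobacillus antri	1	1	100.00	0	1	0
Lactobacillus apodemi	1	1	100.00	0	1	0
Lactobacillus aviarius	15	15	100.00	14	1	0
Lactobacillus coleohominis	2	2	100.00	2	0	0
Lactobacillus crispatus	26	24	92.31	23	1	0
Lactobacillus delbrueckii	30	4	13.33	4	0	0
Lactobacillus equicursoris	2	2	100.00	2	0	0
Lactobacillus frumenti	1	1	100.00	1	0	0
Lactobacillus gallinarum	2	1	50.00	1	0	0
Lactobacillus gasseri	21	21	100.00	1	13	7
Lactobacillus gigeriorum	1	1	100.00	1	0	0
Lactobacillus gorillae	1	1	100.00	1	0	0
Lactobacillus hamsteri	1	1	100.00	1	0	0
Lactobacillus helveticus	23	1	4.35	1	0	0
Lactobacillus hominis	1	1	100.00	0	1	0
Lactobacillus ingluviei	3	1	33.33	1	0	0
Lactobacillus intestinalis	1	1	100.00	0	0	1
Lactobacillus johnsonii	9	9	100.00	1	5	3
Lactobacillus kalixensis	1	1	100.00	0	1	0
Lactobacillus kefiranofaciens	3	1	33.33	1	0	0
Lactobacillus kitasatonis	1	1	100.00	1	0	0
Lactobacillus mucosae	8	8	100.00	8	0	0
Lactobacillus murinus	3	3	100.00	3	0	0
Lactobacillus oris	4	3	75.00	3	0	0
Lactobacillus panis	1	1	100.00	1	0	0
Lactobacillus plantarum	182	147	80.77	147	0	0
Lactobacillus reuteri	30	28	93.33	28	0	0
Lactobacillus rogosae	1	1	100.00	0	1	0
Lactobacillus ruminis	14	12	85.71	12	0	0
Lactobacillus saerimneri	2	1	50.00	1	0	0
Lactobacillus salivarius	14	11	78.57	8	3	0
Lactobacillus secaliphilus	1	1	100.00	1	0	0
Lactobacillus taiwanensis	1	1	100.00	1	0	0
Lactobacillus ultunensis	1	1	100.00	1	0	0
Lactobacillus vaginalis	1	1	100.00	1	0	0
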