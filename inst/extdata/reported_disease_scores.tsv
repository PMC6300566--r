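rank	disease	sensitivity_index	mean_p
1	Dravet syndrome	1718.943899	0.0006
2	HTLV1-Associated Myelopathy (HAM)	626.8531541	0.0016
3	Congenital pain insensitivity with anhidrosis	466.9837537	0.0021
4	Hemorrhagic destruction of the brain, subependymal calcification, and cataracts	418.143026	0.0024
5	Rasmussen encephalitis	293.1481892	0.0034
6	Lattice corneal dystrophies (LCD)	263.6451883	0.0038
7	Subependymal giant cell astrocytoma	246.0470815	0.0041
8	Bipolar Disorder	239.2876	0.0042
9	Familial episodic pain syndrome (FEPS)	231.5937968	0.0043
10	Familial exudative vitreoretinopathy (FEVR)	205.3474156	0.0049
11	Focal dermal hypoplasia	205.3474156	0.0049
12	Choroid plexus papilloma	198.0197413	0.0051
13	Juvenile-onset dystonia	183.6715435	0.0054
14	Prion diseases	175.0031999	0.0057
15	Axenfeld-Rieger syndrome (ARS)	169.1174332	0.0059
16	Congenital stromal corneal dystrophy (CSCD)	169.1174332	0.0059
17	Ring dermoid of cornea	169.1174332	0.0059
18	Stapes ankylosis with broad thumb and toes	169.1174332	0.0059
19	Benign familial neonatal and infantile epilepsies	153.4488999	0.0065
20	Alzheimer's disease	148.6362283	0.0067
21	Neurosis	132.0111986	0.0076
22	Schizophrenia	132.0111986	0.0076
23	Pituitary adenomas	123.9488444	0.0081
24	Febrile seizures	108.3195689	0.0093
25	Episodic ataxias	104.5457633	0.0095
26	Familial or sporadic hemiplegic migraine	104.5457633	0.0095
27	Cerebral amyloid angiopathy (CAA)	89.36992044	0.0112
28	Major depressive disorder	89.36992044	0.0112
29	Epileptic encephalopathy with continuous spike-waves during slow-wave sleep	87.85098473	0.0114
30	Frontotemporal lobar degeneration (FTLD)	75.82609324	0.0132
31	Cerebral palsy	72.92882566	0.0137
32	Generalized epilepsy and paroxysmal dyskinesia (GEPD)	69.3705138	0.0144
33	Amyotrophic lateral sclerosis (ALS)	67.25422275	0.0149
34	Fleck corneal dystrophy (FCD)	63.08690002	0.0158
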