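female_id	male_id	cross_type	compatibility_index	pod_rate_pct	printed_class	female_haplotypes	male_haplotypes
NAU-Rs5	NAU-Rs38	cross	0.88	27.57	Weak Incompatibility	NAU-S17	NAU-S17
NAU-Rs44	NAU-Rs24	cross	0.52	24.09	Weak Incompatibility	NAU-S44	NAU-S44
NAU-Rs7	NAU-Rs9	cross	0.20	12.07	Incompatibility	NAU-S16	NAU-S16
NAU-Rs7	NAU-Rs16	cross	0.17	12.09	Incompatibility	NAU-S16	NAU-S16
NAU-Rs4	NAU-Rs40	cross	0.47	19.75	Incompatibility	NAU-S25	NAU-S25
NAU-Rs40	NAU-Rs4	cross	0.37	21.79	Incompatibility	NAU-S25	NAU-S25
NAU-Rs1	NAU-Rs40	cross	3.76	78.93	Compatibility	NAU-S51	NAU-S25
NAU-Rs44	NAU-Rs30	cross	3.08	74.64	Compatibility	NAU-S44	NAU-S05
NAU-Rs34	NAU-Rs40	cross	2.83	67.90	Compatibility	NAU-S15	NAU-S25
NAU-Rs7	NAU-Rs18	cross	1.85	72.98	Weak Incompatibility	NAU-S16	NAU-S15
NAU-Rs7	NAU-Rs1	cross	2.05	71.75	Compatibility	NAU-S16	NAU-S51
NAU-Rs1	NAU-Rs1	self	0.09	12.40	Self-incompatibility	NAU-S51	NAU-S51
NAU-Rs30	NAU-Rs30	self	0.46	20.69	Self-incompatibility	NAU-S05	NAU-S05
NAU-Rs33	NAU-Rs33	self	0.17	13.22	Self-incompatibility	NAU-S15	NAU-S15
NAU-Rs45	NAU-Rs45	self	0.11	14.59	Self-incompatibility	NAU-S51	NAU-S51
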