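name	gb_frequency_pct	associations
m.8251G>A	6.36	optic neuropathy; type 2 diabetes; Parkinson disease
m.8567T>C	0.18	Parkinson disease; breast cancer
m.12684G>A	0.1	
m.12705C>T	39.5	hereditary optic neuropathy; dystonia; MERRF
m.13062A>G	0.04	
m.13095T>C	0.09	familial sensorineural hearing impairment
m.13105A>G	6.85	antibiotic-induced and non-syndromic deafness
m.310T>C	32.69	Parkinson disease; hereditary optic neuropathy
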