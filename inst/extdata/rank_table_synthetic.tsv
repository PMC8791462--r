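peptide	allele	percentile_rank
FLQFKTWWI	HLA-A*02:01	0.2
YIDNSGKLI	HLA-A*02:01	0.5
AAAAAAAAA	HLA-A*02:01	35
QLWERKLVM	HLA-A*02:01	2.5
FLQFKTWWI	HLA-B*07:02	12
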