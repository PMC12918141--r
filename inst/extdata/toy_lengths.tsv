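gene_id	length
ENSG0000001	1200
ENSG0000002	1800
ENSG0000003	900
ENSG0000004	1500
ENSG0000005	2100
ENSG0000006	800
ENSG0000007	1000
ENSG0000008	1300
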