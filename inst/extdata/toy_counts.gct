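#1.2
8	4
NAME	Description	liver	brain	kidney	lung
ENSG0000001	toy	900	950	880	910
ENSG0000002	toy	850	820	870	905
ENSG0000003	toy	5	700	3	2
ENSG0000004	toy	0	0	650	0
ENSG0000005	toy	30	400	90	800
ENSG0000006	toy	250	20	600	70
ENSG0000007	toy	0	0	0	1
ENSG0000008	toy	2	0	0	0
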