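# candidate reference genes
ENSG0000001
ENSG0000002
ENSG0000003
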