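band,n_mirna_genes
14q32.2,10
14q32.31,44
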