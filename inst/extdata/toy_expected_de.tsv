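gene_id	de
g01	FALSE
g02	FALSE
g03	FALSE
g04	FALSE
g05	FALSE
g06	FALSE
g07	FALSE
g08	FALSE
g09	FALSE
g10	FALSE
g11	TRUE
g12	TRUE
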