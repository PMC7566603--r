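gene_id	c1_r1	c1_r2	c2_r1	c2_r2
g01	10	10	10	10
g02	20	20	20	20
g03	40	40	40	40
g04	80	80	80	80
g05	160	160	160	160
g06	320	320	320	320
g07	640	640	640	640
g08	1280	1280	1280	1280
g09	2560	2560	2560	2560
g10	5120	5120	5120	5120
g11	100	100	400	400
g12	400	400	100	100
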