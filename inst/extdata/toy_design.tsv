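sample_id	condition	replicate
c1_r1	c1	r1
c1_r2	c1	r2
c2_r1	c2	r1
c2_r2	c2	r2
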