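subunit_id	ptm_name	delta_mass	count
a	PCB	586.7	1
b	PCB	586.7	2
b	methylation	14	1
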