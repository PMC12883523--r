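# assembly rules for the synthetic demo inventory
oligomer_states = 1,3
max_variant_substitutions = alpha_variant:3, beta_variant:1
linker_max_copies = 1
allow_cross_source_protomers = TRUE
allow_cross_family_protomers = TRUE
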