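case	lr_plus	prior
missense_abundance_prior21	6	0.21
enzyme_activity_prior25	15	0.25
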