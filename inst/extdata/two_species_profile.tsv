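taxon_id	relative_abundance
T1	0.5
T2	0.5
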