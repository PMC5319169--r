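taxon	genome_size_kb
Viscum_album	565
Viscum_scurruloideum	66
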