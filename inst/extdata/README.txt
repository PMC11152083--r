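Place the deposited focal assembly (GenBank JBBAXF000000000, ~1 GB FASTA,
not bundled) here as JBBAXF000000000.fa to enable the two published-metric
acceptance checks. All other fixtures are generated in code at test time.
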