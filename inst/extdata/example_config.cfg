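correlation: synthetic_spearman_624.tsv
n: 624
gamma: 0.5
partition: instrument_partition.tsv
bootstrap: false
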