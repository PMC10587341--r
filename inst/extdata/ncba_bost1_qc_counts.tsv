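metric	value
homozygous_snps	10813
homozygous_indels	10738
genome_size_bp	2710000000
full_length_ig_sequences	18493
full_length_tr_sequences	18258
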