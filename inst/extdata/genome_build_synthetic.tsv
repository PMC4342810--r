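chrom	length
chr1	10000000
chr2	10000000
chr3	10000000
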