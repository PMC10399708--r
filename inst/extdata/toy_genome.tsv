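chrom	length	cen_start	cen_end
chrA	120000000	55000000	58000000
chrB	100000000	45000000	48000000
chrC	90000000	40000000	43000000
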