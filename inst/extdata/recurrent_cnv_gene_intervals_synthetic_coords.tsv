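gene	chrom	start	end
UGT2B17	4	69400000	69435000
OVOS	12	21500000	21560000
KATNAL2	18	46900000	47050000
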