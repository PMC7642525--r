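subject	family_id	chrom	start	end	call
TWS01	F_TWS01	4	69390000	69440000	loss
TWS06	F_TWS06	4	69390000	69440000	loss
TWS18	F_TWS18	4	69390000	69440000	loss
TWS12	F_TWS12	4	69390000	69440000	loss
XH1535	F_XH1535	12	21490000	21570000	gain
TWS06	F_TWS06	12	21490000	21570000	gain
TWS18	F_TWS18	12	21490000	21570000	gain
TWS22	F_TWS22	12	21490000	21570000	gain
TWS06	F_TWS06	18	46950000	47000000	gain
TWS12	F_TWS12	18	46950000	47000000	gain
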