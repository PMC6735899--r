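name	start_res	end_res	parent
ATPase	1	100	
cleavage_core	101	280	
TOPRIM	110	170	cleavage_core
WHD	190	230	cleavage_core
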