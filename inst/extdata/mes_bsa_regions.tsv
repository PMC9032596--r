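region	chromosome	start_bp	end_bp	vclass
BSA-SNP1-1	1	243149664	251888006	SNP
BSA-SNP4-1	4	162067875	167544471	SNP
BSA-SNP4-2	4	168572722	172116409	SNP
BSA-InDel4-1	4	160984132	164049553	InDel
BSA-InDel4-2	4	165049976	167225404	InDel
BSA-InDel4-3	4	168572674	172533611	InDel
BSA-InDel4-4	4	173979835	176222964	InDel
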