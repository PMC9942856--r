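# Published Blepharisma stoltei repeat-family signatures (TIR/TSD
# strings and microsatellite unit as printed; consensus lengths for
# BogoMITE and BstTc1 are approximate working values).
name	tir	tsd_list	consensus_len	classification	microsat_unit
Bogo	CTCCCCCCCCCCCTCCGTGAGCGAACAAAA	TAA,TTA	2700	DNA/Pogo-Tigger	NA
BogoMITE	CTCCCCCCCCCCCTCCGTGAGCGAACAAAA	TAA,TTA	389	DNA/Pogo-Tigger-MITE	NA
BstTc1	GTACCCCCCCCCTCGTTTGTCGCATTTTCTAGTTTTTT	TATA	1500	DNA/Tc1	GGGAAGGACT
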