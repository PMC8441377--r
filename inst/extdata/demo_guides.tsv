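id	side	protospacer	strand	cut_site
US-1	upstream	GTGCGCACTTTCTGATGGAC	+	
US-2	upstream	CGGCGGCTCCTAACACTAGA	+	
US-3	upstream	AGGAGTATGCGCTCCACACC	+	
DS-1	downstream	GGCTCGCGACGTGGATCTAA	+	240
DS-2	downstream	TAGGGGCTGGTGAAGGGTCC	+	
DS-3	downstream	TACCGAAATTATTCACGATG	-	
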