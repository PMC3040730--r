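# Screening-line registry for sea anemone toxin scaffolds, SRDA("C.") patterns.
# Columns: id, query, enabled (1/0). Compound queries use residue-count syntax.
# Motifs 0 and 14 are too degenerate for bank mining and ship disabled;
# the compound motif K covers cysteine-free cytolysins in their place.
id	query	enabled
motif 1	C1C##C6C#CC	1
motif 2	C1C##C9C#CC#.	1
motif 3	C8C#C*C3C#C.	1
motif 4	C8C*C#C*C3C	1
motif 5	C8C#C*C1C#C#.	1
motif 6	CC#C#CC*C1C*C.	1
motif 7	CC1C*C*C*C*C1C#.	1
motif 8	CC1C#C5C*C#.	1
motif 9	C6C*C*C*C6C#.	1
motif 10	C8C3C#C.	1
motif 11	C#C#C#C#C#C#C#C#.	1
motif 12	C6C#C#C1C*C1C	1
motif 13	C#C#C#C#.	1
motif 0	###.	0
motif 14	##C	0
motif K	K >= 6 AND C <= 2	1
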