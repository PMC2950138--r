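probe_id	upstream_seq	downstream_seq	junction_pos
FCGR3B_1	CGTGGAGATAATATTGAGGCAGAGACACTGCTAGTGGTCA	AAGATTTGAAAGGACAACTTTCTGTGTGCAGGCAGGGC	-256
FCGR3B_2	CCGACGTACGTATCTAAATCCAGGAGATGGGGGCAAGCATCCTGGGAA	AGCTGAGGGCACACTCTGGCAGATTCTGTGTG	-390
FCGR3B_3	CCCCACCTTGCCTCCAGGCTCTTTCCTTCCTA	TTCCTGTTCTATGGTGGGGCTCCATTGCGAGA	-149
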