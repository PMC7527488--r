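motif_length	class	count
2	Dinucleotide	15165
3	Trinucleotide	6570
4	Tetranucleotide	659
5	Pentanucleotide	116
6	Hexanucleotide	238
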