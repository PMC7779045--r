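# CDS coordinates of the 13 protein-coding genes on the human mitochondrial
# genome record NC_001807.4 (16,571 bp; shipped as seqinr's humanMito.fasta).
# Coordinates are 1-based inclusive. Derived programmatically: each gene is
# the unique clean open reading frame (vertebrate mitochondrial code, correct
# protein length, valid start, terminal stop after A-completion where the
# feature ends mid-codon) found by scanning around the canonical human mtDNA
# gene positions; on this record every gene sits exactly one base downstream
# of its rCRS (NC_012920.1) coordinate.
gene	start	end	strand
MT-ND1	3308	4263	+
MT-ND2	4471	5512	+
MT-CO1	5905	7446	+
MT-CO2	7587	8270	+
MT-ATP8	8367	8573	+
MT-ATP6	8528	9208	+
MT-CO3	9208	9991	+
MT-ND3	10060	10405	+
MT-ND4L	10471	10767	+
MT-ND4	10761	12138	+
MT-ND5	12338	14149	+
MT-ND6	14150	14674	-
MT-CYB	14748	15888	+
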