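>AluY_synthetic_consensus synthetic 288 bp AluY-like consensus (left arm, A5TACA5 linker, right arm, poly-A tail)
GCCGTCATGAGGTTCAGGCGTATAGAACTCGACAGGGCCGATCGGTATTGAACGGTGGCG
AAGAGTTGGAGACACCCTAGGCCCTGGCCGAGTCACCTTTGCACCGCAGGCCCGGGTTAA
AAAAATACAAAAACGTGTCTGAGCCGCAGAGGGGAGCTCTCGTATTGTAGCTCGAGAAGT
CCCACAGCCGGCGGGGGCAGTACGGGTGAACTCTTGTTGGCCTCACGTAGCGCAACAAAC
CATCTTTCCGACTACCTATCTCTAAAAAAAAAAAAAAAAAAAAAAAAA
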