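>alpha_like_synthetic
GACTGATTGACTTGCGGATTGACAGGCCACGCCTTGTTGCAGGACACCCCACATAGCAGTAATCTCTTGAGCGGAGCCGGCCGTTTTATCACTTCCTGACGACGACCGGATACTCAGCGGAGGCCCTATGCAATCCGGCAATTCAGCATGTATCCTGCGCACGAAACAAGT
>hsat_like_synthetic
CTTCACCACCTTCGAATATTTTAGAGTCAGTCACACTATTCAAATATA
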