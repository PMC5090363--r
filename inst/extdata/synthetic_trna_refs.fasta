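>tRNA-Asp-synthetic synthetic tRNA-like reference, C38 target
GTCGTTGTAGTATAGTGGTAAGTATTCCCGCCTGTCACGCGGGAGACCGGGGTTCGATTC
CCCGCAACGGA
>tRNA-Gly-synthetic synthetic tRNA-like reference, C38 target
GCATTGGTGGTTCAGTGGTAGAATTCTCGCCTGCCACCGGGGAGGCCCGGGTTCGATTCC
CGGCCAATGCA
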