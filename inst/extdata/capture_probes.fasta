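>C9 capture
AGGAAATGCATTGGTCGTGTAA
>C10 capture
GATGATAGGAGTATTGGGAC
>scrambled control
GTGAGGCGTTGTAAGAGTGGTTAAG
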