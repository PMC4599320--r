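# Example primer pairs for 16S rRNA variable-region extraction.
# Format: name<TAB>forward<TAB>reverse (each written 5'->3' on its strand).
V1V3	AGAGTTTGATCMTGGCTCAG	ATTACCGCGGCTGCTGG
V3V5	CCTACGGGAGGCAGCAG	CCGTCAATTCMTTTRAGT
V6V9	AAACTYAAAKGAATTGACGG	TACGGYTACCTTGTTACGACTT
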