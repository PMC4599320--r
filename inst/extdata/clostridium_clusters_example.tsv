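# Example species -> Clostridium cluster lookup (edit to taste).
# Format: species<TAB>cluster. A small illustrative subset of the
# traditional 16S-similarity clusters.
Clostridium butyricum	Cluster I
Clostridium perfringens	Cluster I
Clostridium beijerinckii	Cluster I
Clostridium difficile	Cluster XI
Clostridium sordellii	Cluster XI
Faecalibacterium prausnitzii	Cluster IV
Ruminococcus bromii	Cluster IV
Blautia obeum	Cluster XIVa
Roseburia intestinalis	Cluster XIVa
Eubacterium rectale	Cluster XIVa
Coprococcus eutactus	Cluster XIVa
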