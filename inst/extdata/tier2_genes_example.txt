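# Example Tier-2 candidate list: genes with common LDL-C-associated
# GWAS variants, tested for rare-variant burden as a candidate set.
# Supply your own list for real analyses.
SORT1
APOB
ABCG5
ABCG8
HMGCR
MYLIP
HFE
ST3GAL4
NYNRIN
LDLR
APOE
INSIG2
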