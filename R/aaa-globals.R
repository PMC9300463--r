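# Shared constants (this file collates before the modules that use them).

# The 20 canonical amino acids; X (ambiguity) is tolerated by the aligner.
AA_ALPHABET20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
AA_ALPHABET21 <- c(AA_ALPHABET20, "X")
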