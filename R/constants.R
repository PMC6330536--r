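# Shared constants: nucleotide alphabet, codon space, genetic code, and
# per-codon synonymous site counts (computed once at install).

DNA_BASES4 <- c("A", "C", "G", "T")

ALL_CODONS <- as.vector(outer(outer(DNA_BASES4, DNA_BASES4, paste0),
                              DNA_BASES4, paste0))
STOP_CODONS <- c("TAA", "TAG", "TGA")
NON_STOP_CODONS <- setdiff(ALL_CODONS, STOP_CODONS)

GENETIC_CODE_VEC <- Biostrings::GENETIC_CODE

# Synonymous site count of one codon: per position, (# synonymous one-step
# changes)/3; changes into stop codons count as non-synonymous.
syn_sites_one <- function(codon) {
  aa <- GENETIC_CODE_VEC[codon]
  s <- 0
  for (pos in 1:3) {
    for (b in setdiff(DNA_BASES4, substr(codon, pos, pos))) {
      alt <- codon
      substr(alt, pos, pos) <- b
      if (!alt %in% STOP_CODONS && GENETIC_CODE_VEC[alt] == aa) s <- s + 1 / 3
    }
  }
  s
}

SYN_SITES <- vapply(NON_STOP_CODONS, syn_sites_one, numeric(1))
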