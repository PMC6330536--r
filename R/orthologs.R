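#' Load and validate coding sequences for Ks analysis
#'
#' Reads a CDS FASTA, strips a terminal stop codon when present, and
#' excludes (with a warning) sequences whose length is not a multiple of
#' three, that contain an internal stop codon, or that fall below
#' `min_codons`.  Exact duplicate sequences beyond the first are also
#' dropped, a deterministic stand-in for redundancy clustering.
#'
#' @param path FASTA file path, or a [Biostrings::DNAStringSet].
#' @param min_codons Minimum CDS length in codons (default 30).
#' @return A validated `DNAStringSet`.
#' @export
read_cds <- function(path, min_codons = 30) {
  x <- if (inherits(path, "DNAStringSet")) path else
    Biostrings::readDNAStringSet(path)
  if (is.null(names(x)) || anyDuplicated(names(x)))
    stop("CDS sequences must carry unique names", call. = FALSE)
  names(x) <- sub("\\s.*$", "", names(x))
  seqs <- as.character(x)
  # strip one terminal stop codon if present
  lastc <- substring(seqs, nchar(seqs) - 2, nchar(seqs))
  has_stop <- nchar(seqs) %% 3 == 0 & lastc %in% STOP_CODONS
  seqs[has_stop] <- substring(seqs[has_stop], 1, nchar(seqs[has_stop]) - 3)
  bad_frame <- nchar(seqs) %% 3 != 0
  internal_stop <- vapply(seqs, function(s) {
    cod <- codon_split(s)
    any(cod %in% STOP_CODONS)
  }, logical(1), USE.NAMES = FALSE)
  short <- nchar(seqs) / 3 < min_codons
  drop <- bad_frame | internal_stop | short
  if (any(drop))
    warning(sum(drop), " sequence(s) excluded (frame/internal stop/length): ",
            paste(head(names(x)[drop], 5), collapse = ", "), call. = FALSE)
  seqs <- seqs[!drop]; nm <- names(x)[!drop]
  dup <- duplicated(seqs)
  if (any(dup))
    warning(sum(dup), " exact duplicate sequence(s) removed", call. = FALSE)
  Biostrings::DNAStringSet(setNames(seqs[!dup], nm[!dup]))
}

codon_split <- function(s) {
  n <- nchar(s) %/% 3
  substring(s, 3 * seq_len(n) - 2, 3 * seq_len(n))
}

#' Pair orthologs by reciprocal best hit of translated sequences
#'
#' Scores every cross-set pair by global protein alignment (BLOSUM62,
#' affine gaps: opening 10, extension 0.5) of the translations and keeps a
#' pair when each sequence is the unique best hit of the other; ties for
#' best hit drop the query.
#'
#' @param set_a,set_b Validated `DNAStringSet`s from [read_cds()].
#' @return data.frame: `id_a`, `id_b`, `score`.
#' @export
reciprocal_best_hits <- function(set_a, set_b) {
  aa_a <- suppressWarnings(Biostrings::translate(set_a))
  aa_b <- suppressWarnings(Biostrings::translate(set_b))
  scores <- matrix(NA_real_, length(set_a), length(set_b),
                   dimnames = list(names(set_a), names(set_b)))
  for (i in seq_along(aa_a)) {
    scores[i, ] <- Biostrings::pairwiseAlignment(
      aa_b, aa_a[[i]], type = "global", substitutionMatrix = "BLOSUM62",
      gapOpening = 10, gapExtension = 0.5, scoreOnly = TRUE)
  }
  best_unique <- function(v) {
    m <- max(v)
    w <- which(v == m)
    if (length(w) == 1) w else NA_integer_
  }
  best_a <- apply(scores, 1, best_unique)  # best B for each A
  best_b <- apply(scores, 2, best_unique)  # best A for each B
  keep <- which(!is.na(best_a) & !is.na(best_b[best_a]) &
                  best_b[best_a] == seq_along(best_a))
  data.frame(id_a = names(set_a)[keep], id_b = names(set_b)[best_a[keep]],
             score = scores[cbind(keep, best_a[keep])],
             stringsAsFactors = FALSE)
}

#' Align an ortholog pair codon-wise via its protein alignment
#'
#' Globally aligns the two translations (same scoring as
#' [reciprocal_best_hits()]), back-translates the alignment codon-wise,
#' and removes every column containing a gap.
#'
#' @param cds_a,cds_b In-frame CDS character strings (or `DNAString`s).
#' @return list of class `codon_alignment`: `codons_a`, `codons_b`
#'   (equal-length codon vectors), `length` (in codons), `aligned_a`,
#'   `aligned_b` (codon counts of each input that landed in gap-free
#'   columns).
#' @export
codon_align <- function(cds_a, cds_b) {
  cds_a <- as.character(cds_a); cds_b <- as.character(cds_b)
  stopifnot(nchar(cds_a) %% 3 == 0, nchar(cds_b) %% 3 == 0)
  ca <- codon_split(cds_a); cb <- codon_split(cds_b)
  aa <- Biostrings::translate(Biostrings::DNAString(cds_a))
  ab <- Biostrings::translate(Biostrings::DNAString(cds_b))
  aln <- Biostrings::pairwiseAlignment(
    aa, ab, type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ia <- ib <- 0L
  keep_a <- integer(0); keep_b <- integer(0)
  for (k in seq_along(pa)) {
    ga <- pa[k] == "-"; gb <- pb[k] == "-"
    if (!ga) ia <- ia + 1L
    if (!gb) ib <- ib + 1L
    if (!ga && !gb) {
      keep_a <- c(keep_a, ia); keep_b <- c(keep_b, ib)
    }
  }
  if (length(keep_a) == 0)
    stop("alignment has no gap-free codon columns", call. = FALSE)
  structure(list(codons_a = ca[keep_a], codons_b = cb[keep_b],
                 length = length(keep_a)),
            class = "codon_alignment")
}

#' Coverage filter on an ortholog pair's alignment
#'
#' Keeps a pair only when the aligned (gap-free) codon columns exceed
#' `min_cov` of the reference ortholog's length — the "exceeding 50% of
#' the reference ortholog" rule, strict at the boundary.
#'
#' @param aln A `codon_alignment`.
#' @param ref_len_codons Length of the reference ortholog in codons.
#' @param min_cov Coverage threshold (default 0.5).
#' @return `TRUE` to keep the pair.
#' @export
length_filter <- function(aln, ref_len_codons, min_cov = 0.5) {
  stopifnot(inherits(aln, "codon_alignment"), ref_len_codons > 0)
  aln$length / ref_len_codons > min_cov
}
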