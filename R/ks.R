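#' Nei-Gojobori synonymous divergence of a codon alignment
#'
#' Counting estimator of substitutions per synonymous site.  Synonymous
#' *sites* per codon are the sum over its three positions of the fraction
#' of the three possible single-base changes that are synonymous (standard
#' nuclear code), averaged over the two sequences.  Synonymous
#' *differences* between a codon pair are averaged with equal weight over
#' all minimal mutational pathways between them, excluding pathways that
#' pass through a stop codon (if every pathway is blocked, all pathways
#' are used).  The proportion `ps = sd / S` is corrected for multiple hits
#' with the Jukes-Cantor formula `Ks = -(3/4) ln(1 - (4/3) ps)`.
#'
#' @param aln A `codon_alignment` from [codon_align()], or a list with
#'   `codons_a` and `codons_b` codon vectors of equal length.
#' @return list of class `ks_estimate`: `S` (synonymous sites), `sd`
#'   (synonymous differences), `ps`, `ks`, `n_codons`.
#' @examples
#' aln <- codon_align(strrep("GGT", 6), paste0(strrep("GGT", 5), "GGC"))
#' nei_gojobori_ks(aln)$ks   # ~0.1885
#' @export
nei_gojobori_ks <- function(aln) {
  ca <- toupper(aln$codons_a); cb <- toupper(aln$codons_b)
  stopifnot(length(ca) == length(cb), length(ca) >= 1)
  if (any(c(ca, cb) %in% STOP_CODONS))
    stop("alignment contains stop codons", call. = FALSE)
  S <- (sum(SYN_SITES[ca]) + sum(SYN_SITES[cb])) / 2
  if (S <= 0) stop("no synonymous sites in alignment", call. = FALSE)
  sd_total <- sum(vapply(seq_along(ca), function(i)
    codon_pair_stats(ca[i], cb[i])["sd"], numeric(1)))
  ps <- sd_total / S
  if (ps >= 0.75)
    stop("ps >= 3/4: synonymous sites saturated, Ks undefined",
         call. = FALSE)
  structure(list(S = S, sd = sd_total, ps = ps,
                 ks = -0.75 * log(1 - 4 / 3 * ps), n_codons = length(ca)),
            class = "ks_estimate")
}

# genetic code over the 64 codons, from Biostrings
codon_aa <- function(codon) GENETIC_CODE_VEC[codon]

# Pathway-averaged synonymous/non-synonymous difference counts between two
# codons, memoised.
codon_pair_stats <- function(c1, c2) {
  if (c1 == c2) return(c(sd = 0, nd = 0))
  key <- paste0(c1, c2)
  hit <- .ks_cache[[key]]
  if (!is.null(hit)) return(hit)
  diffs <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  perms <- PERMS[[length(diffs)]]
  syn <- nons <- numeric(0)
  for (p in seq_len(nrow(perms))) {
    ord <- diffs[perms[p, ]]
    cur <- c1
    s <- ns <- 0
    blocked <- FALSE
    for (pos in ord) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(c2, pos, pos)
      if (nxt %in% STOP_CODONS) { blocked <- TRUE; break }
      if (codon_aa(nxt) == codon_aa(cur)) s <- s + 1 else ns <- ns + 1
      cur <- nxt
    }
    if (!blocked) { syn <- c(syn, s); nons <- c(nons, ns) }
  }
  if (length(syn) == 0) {
    # all pathways pass through a stop; fall back to unrestricted averaging
    for (p in seq_len(nrow(perms))) {
      ord <- diffs[perms[p, ]]
      cur <- c1; s <- ns <- 0
      for (pos in ord) {
        nxt <- cur
        substr(nxt, pos, pos) <- substr(c2, pos, pos)
        if (!nxt %in% STOP_CODONS && codon_aa(nxt) == codon_aa(cur))
          s <- s + 1 else ns <- ns + 1
        cur <- nxt
      }
      syn <- c(syn, s); nons <- c(nons, ns)
    }
  }
  out <- c(sd = mean(syn), nd = mean(nons))
  .ks_cache[[key]] <- out
  out
}

.ks_cache <- new.env(parent = emptyenv())

PERMS <- list(matrix(1L, 1, 1),
              rbind(c(1L, 2L), c(2L, 1L)),
              rbind(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                    c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))

#' Date a divergence from a set of Ks values
#'
#' `T_div = median Ks / (2 * rate)` years under a molecular clock, using
#' the generic grass synonymous substitution rate 6.5e-9 per site per
#' year by default.  The lower median is used for even counts.
#'
#' @param ks_values Numeric vector of finite Ks estimates (>= 1 value).
#' @param rate Substitutions per synonymous site per year.
#' @return list of class `divergence_estimate`: `median_ks`, `n_pairs`,
#'   `years`, `mya` (rounded to 3 decimals).
#' @examples
#' divergence_time(0.010)$mya   # 0.769
#' @export
divergence_time <- function(ks_values, rate = 6.5e-9) {
  ks <- ks_values[is.finite(ks_values)]
  if (length(ks) == 0) stop("no finite Ks values", call. = FALSE)
  s <- sort(ks)
  m <- s[ceiling(length(s) / 2)]  # lower median for even counts
  years <- m / (2 * rate)
  structure(list(median_ks = m, n_pairs = length(ks), years = years,
                 mya = round(years / 1e6, 3)),
            class = "divergence_estimate")
}

#' Full Ks dating pipeline for two CDS sets
#'
#' Reciprocal-best-hit pairing, codon alignment, coverage filtering
#' against set B (the reference ortholog set), Nei-Gojobori Ks per pair,
#' and median-Ks dating.  Pairs with saturated synonymous sites are
#' reported with `NA` Ks and excluded from dating.
#'
#' @param set_a,set_b CDS FASTA paths or `DNAStringSet`s (validated via
#'   [read_cds()]).
#' @param min_cov Coverage threshold of [length_filter()].
#' @param rate Clock rate for [divergence_time()].
#' @param min_codons Minimum CDS length.
#' @return list: `pairs` (data.frame `id_a`, `id_b`, `S`, `sd`, `ps`,
#'   `ks`), `divergence` (a `divergence_estimate`).
#' @export
ks_pipeline <- function(set_a, set_b, min_cov = 0.5, rate = 6.5e-9,
                        min_codons = 30) {
  a <- read_cds(set_a, min_codons = min_codons)
  b <- read_cds(set_b, min_codons = min_codons)
  rbh <- reciprocal_best_hits(a, b)
  rows <- list()
  for (i in seq_len(nrow(rbh))) {
    aln <- codon_align(a[[rbh$id_a[i]]], b[[rbh$id_b[i]]])
    if (!length_filter(aln, length(b[[rbh$id_b[i]]]) / 3, min_cov = min_cov))
      next
    est <- tryCatch(nei_gojobori_ks(aln), error = function(e) NULL)
    rows[[length(rows) + 1]] <- data.frame(
      id_a = rbh$id_a[i], id_b = rbh$id_b[i],
      S = if (is.null(est)) NA_real_ else est$S,
      sd = if (is.null(est)) NA_real_ else est$sd,
      ps = if (is.null(est)) NA_real_ else est$ps,
      ks = if (is.null(est)) NA_real_ else est$ks,
      stringsAsFactors = FALSE)
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id_a = character(0), id_b = character(0), S = numeric(0),
               sd = numeric(0), ps = numeric(0), ks = numeric(0))
  div <- if (any(is.finite(pairs$ks))) divergence_time(pairs$ks, rate = rate)
         else NULL
  list(pairs = pairs, divergence = div)
}

#' Simulate codon alignments with a known synonymous divergence
#'
#' Generates ancestor sequences from fourfold-degenerate codon families
#' (Ala/Gly/Pro/Thr/Val), whose third positions are exactly one
#' synonymous site each, then evolves the third positions of two
#' descendant copies under the Jukes-Cantor model so that the expected
#' pairwise synonymous divergence equals `ks`.  Used to check estimator
#' recovery.
#'
#' @param n_pairs Number of alignments.
#' @param n_codons Codons per alignment.
#' @param ks True expected synonymous substitutions per site between the
#'   two descendants.
#' @return List of `codon_alignment`-compatible lists.
#' @export
simulate_ks_pairs <- function(n_pairs, n_codons, ks) {
  fam <- c("GC", "GG", "CC", "AC", "GT")  # Ala Gly Pro Thr Val prefixes
  t_branch <- ks / 2
  p_change <- 3 / 4 * (1 - exp(-4 * t_branch / 3))
  lapply(seq_len(n_pairs), function(i) {
    pre <- sample(fam, n_codons, replace = TRUE)
    third <- sample(DNA_BASES4, n_codons, replace = TRUE)
    evolve <- function(x) {
      hit <- runif(n_codons) < p_change
      x[hit] <- vapply(x[hit], function(b)
        sample(setdiff(DNA_BASES4, b), 1), character(1))
      x
    }
    list(codons_a = paste0(pre, evolve(third)),
         codons_b = paste0(pre, evolve(third)))
  })
}
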