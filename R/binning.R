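#' Segregation-ratio and completeness filter for single-dose markers
#'
#' A genuine single-dose marker segregates 1:1 in the F1, so its presence
#' fraction among non-missing progeny should sit near 0.5; markers outside
#' `[lo, hi]` (default 0.3-0.7) are discarded, as are markers genotyped in
#' fewer than `min_genotyped` individuals (default 39).  This is the stage
#' that removes most multi-dose sites admitted by the ratio window (a
#' duplex marker is present in ~11/14 of progeny).
#'
#' @param genotypes Integer matrix (markers x progeny) of 1/0/NA calls, or
#'   a single vector.
#' @param lo,hi Inclusive bounds on the presence fraction.
#' @param min_genotyped Minimum non-missing progeny count.
#' @return Logical vector over markers (all-missing markers fail).
#' @export
segregation_filter <- function(genotypes, lo = 0.3, hi = 0.7,
                               min_genotyped = 39) {
  if (is.null(dim(genotypes))) genotypes <- matrix(genotypes, nrow = 1)
  n_ok <- rowSums(!is.na(genotypes))
  frac <- rowSums(genotypes == 1L, na.rm = TRUE) / n_ok
  pass <- n_ok >= min_genotyped & !is.na(frac) & frac >= lo & frac <= hi
  pass & n_ok > 0
}

#' Collapse co-segregating markers into bins
#'
#' Two markers co-segregate when, over jointly non-missing progeny, their
#' calls conflict at no more than `max_conflicts` positions in *either
#' phase orientation*: a presence/absence vector and its complement encode
#' the same locus on opposite homolog phases, so complements are merged
#' (repulsion phase).  Bins are formed by greedy leader clustering over
#' markers sorted by id: each marker joins the first bin whose leader it
#' is compatible with, or founds a new bin.  Markers with a missing-call
#' fraction above `max_missing_frac` are ineligible and returned
#' separately; eligible markers are partitioned exactly.
#'
#' @param genotypes Integer matrix (markers x progeny), rownames = marker
#'   ids.
#' @param max_conflicts Maximum tolerated conflicting calls (default 0).
#' @param max_missing_frac Maximum missing fraction for binnable markers.
#' @param min_shared Minimum jointly non-missing progeny for two markers
#'   to be comparable (markers sharing fewer never co-bin).
#' @return A list of class `marker_bins`: `bins` (data.frame `bin_id`,
#'   `representative`, `n_markers`, `members` comma-joined), `membership`
#'   (data.frame `marker_id`, `bin_id`, `flipped`), `consensus` (matrix
#'   bins x progeny), `excluded` (ids failing the missing cap).
#' @export
build_bins <- function(genotypes, max_conflicts = 0, max_missing_frac = 0.10,
                       min_shared = 1) {
  stopifnot(is.matrix(genotypes), !is.null(rownames(genotypes)))
  miss <- rowMeans(is.na(genotypes))
  excluded <- rownames(genotypes)[miss > max_missing_frac]
  g <- genotypes[miss <= max_missing_frac, , drop = FALSE]
  g <- g[order(rownames(g)), , drop = FALSE]
  n <- nrow(g)
  if (n == 0)
    return(structure(list(bins = NULL, membership = NULL, consensus = NULL,
                          excluded = excluded), class = "marker_bins"))
  P <- (g == 1L) & !is.na(g)
  A <- (g == 0L) & !is.na(g)
  storage.mode(P) <- "numeric"; storage.mode(A) <- "numeric"
  lead <- integer(0)               # row indices of bin leaders
  bin_of <- integer(n)
  flip <- logical(n)
  LP <- matrix(0, 0, ncol(g)); LA <- matrix(0, 0, ncol(g))
  for (i in seq_len(n)) {
    if (length(lead) > 0) {
      mism <- LP %*% A[i, ] + LA %*% P[i, ]
      shared <- (LP + LA) %*% (P[i, ] + A[i, ])
      conf <- pmin(mism, shared - mism)
      ok <- which(shared >= min_shared & conf <= max_conflicts)
    } else ok <- integer(0)
    if (length(ok) > 0) {
      b <- ok[1]
      bin_of[i] <- b
      flip[i] <- mism[b] > shared[b] - mism[b]
    } else {
      lead <- c(lead, i)
      LP <- rbind(LP, P[i, ]); LA <- rbind(LA, A[i, ])
      bin_of[i] <- length(lead)
      flip[i] <- FALSE
    }
  }
  ids <- rownames(g)
  n_bins <- length(lead)
  consensus <- matrix(NA_integer_, n_bins, ncol(g),
                      dimnames = list(sprintf("bin%04d", seq_len(n_bins)),
                                      colnames(g)))
  reps <- character(n_bins)
  members <- character(n_bins)
  for (b in seq_len(n_bins)) {
    m <- which(bin_of == b)
    gm <- g[m, , drop = FALSE]
    fl <- flip[m]
    gm[fl, ] <- 1L - gm[fl, , drop = FALSE]
    pres <- colSums(gm == 1L, na.rm = TRUE)
    abs_ <- colSums(gm == 0L, na.rm = TRUE)
    consensus[b, ] <- ifelse(pres + abs_ == 0, NA_integer_,
                             ifelse(pres > abs_, 1L,
                                    ifelse(abs_ > pres, 0L, NA_integer_)))
    reps[b] <- choose_representative(ids[m], rowSums(is.na(gm)))
    members[b] <- paste(ids[m], collapse = ",")
  }
  structure(list(
    bins = data.frame(bin_id = rownames(consensus), representative = reps,
                      n_markers = tabulate(bin_of, n_bins),
                      members = members, stringsAsFactors = FALSE),
    membership = data.frame(marker_id = ids,
                            bin_id = rownames(consensus)[bin_of],
                            flipped = flip, stringsAsFactors = FALSE),
    consensus = consensus, excluded = excluded), class = "marker_bins")
}

#' Pick a bin's representative marker
#'
#' The member with the least missing data; ties break to the
#' lexicographically smallest marker id.
#'
#' @param marker_ids Member ids.
#' @param n_missing Missing-call count per member (same order).
#' @return A single marker id.
#' @export
choose_representative <- function(marker_ids, n_missing) {
  if (length(marker_ids) == 0) stop("empty bin", call. = FALSE)
  stopifnot(length(marker_ids) == length(n_missing))
  cand <- marker_ids[n_missing == min(n_missing)]
  sort(cand)[1]
}
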