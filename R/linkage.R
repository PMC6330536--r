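#' Two-point linkage statistics for 1:1 pseudo-testcross markers
#'
#' For two presence/absence vectors sharing `n` non-missing progeny with
#' `M` mismatching calls, phase is resolved by mismatch minimisation:
#' `R = min(M, n - M)` recombinants, `rf = R / n`, and
#' `LOD = (n - R) log10(2(1 - rf)) + R log10(2 rf)` (with the `R = 0`
#' limit `n log10 2`), the log10 likelihood ratio of linkage at `rf`
#' against free recombination.
#'
#' @param a,b Genotype vectors of 1/0/NA calls.
#' @param min_shared Minimum jointly non-missing progeny; below it the
#'   pair is not scored (returns `NA` statistics).
#' @return A one-row data.frame: `n`, `R`, `rf`, `lod`.
#' @examples
#' pairwise_linkage(rep(c(1, 0), 25), rep(c(1, 0), 25))  # LOD = 50 log10(2)
#' @export
pairwise_linkage <- function(a, b, min_shared = 10) {
  ok <- !is.na(a) & !is.na(b)
  n <- sum(ok)
  if (n < min_shared)
    return(data.frame(n = n, R = NA_integer_, rf = NA_real_, lod = NA_real_))
  M <- sum(a[ok] != b[ok])
  R <- min(M, n - M)
  data.frame(n = n, R = R, rf = R / n, lod = lod_score(n, R))
}

lod_score <- function(n, R) {
  rf <- R / n
  term <- ifelse(R == 0, 0, R * log10(2 * rf))
  (n - R) * log10(2 * (1 - rf)) + term
}

#' All pairwise linkage statistics for a bin consensus matrix
#'
#' Vectorised two-point scan over every bin pair with at least
#' `min_shared` jointly non-missing progeny; identical mathematics to
#' [pairwise_linkage()].
#'
#' @param consensus Matrix (bins x progeny) of 1/0/NA consensus calls with
#'   rownames.
#' @inheritParams pairwise_linkage
#' @return data.frame: `a`, `b` (bin ids), `n`, `R`, `rf`, `lod`.
#' @export
linkage_pairs <- function(consensus, min_shared = 10) {
  stopifnot(is.matrix(consensus), !is.null(rownames(consensus)))
  P <- (consensus == 1L) & !is.na(consensus)
  A <- (consensus == 0L) & !is.na(consensus)
  storage.mode(P) <- "numeric"; storage.mode(A) <- "numeric"
  match_ct <- tcrossprod(P) + tcrossprod(A)
  nn <- tcrossprod(P + A)
  M <- nn - match_ct
  idx <- which(upper.tri(nn) & nn >= min_shared, arr.ind = TRUE)
  if (nrow(idx) == 0)
    return(data.frame(a = character(0), b = character(0), n = integer(0),
                      R = integer(0), rf = numeric(0), lod = numeric(0)))
  n <- nn[idx]
  R <- pmin(M[idx], n - M[idx])
  data.frame(a = rownames(consensus)[idx[, 1]],
             b = rownames(consensus)[idx[, 2]],
             n = as.integer(n), R = as.integer(R), rf = R / n,
             lod = lod_score(n, R), stringsAsFactors = FALSE)
}

#' Sort bins into linkage groups by LOD threshold with a rescue pass
#'
#' Groups are the connected components of the graph whose edges are pairs
#' with `LOD >= lod_cutoff` (single-linkage transitive closure).  Bins
#' left on their own are then attached to the group holding their single
#' strongest link when that link's LOD reaches `rescue_cutoff`
#' (interpreting the strongest-cross-link rescue rule); the rest stay
#' ungrouped.
#'
#' @param pairs data.frame from [linkage_pairs()].
#' @param bin_ids All bin ids (so isolated bins are reported too).
#' @param lod_cutoff Grouping threshold (default 6).
#' @param rescue_cutoff Rescue threshold for unplaced bins (default 4).
#' @return data.frame: `bin_id`, `group` (`NA` when ungrouped),
#'   `rescued`.
#' @export
group_bins <- function(pairs, bin_ids, lod_cutoff = 6, rescue_cutoff = 4) {
  strong <- pairs[!is.na(pairs$lod) & pairs$lod >= lod_cutoff, , drop = FALSE]
  gr <- igraph::graph_from_data_frame(strong[, c("a", "b")],
                                      directed = FALSE,
                                      vertices = data.frame(name = bin_ids))
  comp <- igraph::components(gr)
  member <- comp$membership[bin_ids]
  grouped <- comp$csize[member] >= 2
  group <- ifelse(grouped, paste0("LG", member), NA_character_)
  rescued <- rep(FALSE, length(bin_ids))
  names(rescued) <- bin_ids
  loose <- bin_ids[!grouped]
  if (length(loose) > 0 && nrow(pairs) > 0) {
    for (b in loose) {
      e <- pairs[(pairs$a == b | pairs$b == b) & !is.na(pairs$lod), ,
                 drop = FALSE]
      if (nrow(e) == 0) next
      other <- ifelse(e$a == b, e$b, e$a)
      tg <- group[match(other, bin_ids)]
      e <- e[!is.na(tg), , drop = FALSE]; tg <- tg[!is.na(tg)]
      if (nrow(e) == 0) next
      best <- which.max(e$lod)
      if (e$lod[best] >= rescue_cutoff) {
        group[match(b, bin_ids)] <- tg[best]
        rescued[b] <- TRUE
      }
    }
  }
  # relabel groups in a stable, size-independent order of first appearance
  lab <- unique(group[!is.na(group)])
  idx <- match(group, lab)
  group <- ifelse(is.na(idx), NA_character_, sprintf("LG%03d", idx))
  data.frame(bin_id = bin_ids, group = group, rescued = unname(rescued),
             stringsAsFactors = FALSE)
}

#' Order the bins of one linkage group and assign Kosambi positions
#'
#' Seriation heuristic replacing multipoint regression mapping: start from
#' the pair with maximal LOD, greedily extend the chain at either end with
#' the bin of minimal recombination fraction to that end, then refine with
#' 2-opt segment reversals minimising the sum of adjacent recombination
#' fractions.  Positions are the cumulative Kosambi distances of adjacent
#' pairs, starting at 0.
#'
#' @param ids Bin ids of the group (>= 2).
#' @param pairs data.frame from [linkage_pairs()] covering the group.
#' @return data.frame: `bin_id` in map order, `position` in cM.
#' @export
order_group <- function(ids, pairs) {
  stopifnot(length(ids) >= 2)
  k <- length(ids)
  rf <- matrix(0.5, k, k, dimnames = list(ids, ids))
  lod <- matrix(-Inf, k, k, dimnames = list(ids, ids))
  sel <- pairs$a %in% ids & pairs$b %in% ids & !is.na(pairs$lod)
  p <- pairs[sel, , drop = FALSE]
  rf[cbind(p$a, p$b)] <- p$rf; rf[cbind(p$b, p$a)] <- p$rf
  lod[cbind(p$a, p$b)] <- p$lod; lod[cbind(p$b, p$a)] <- p$lod
  diag(rf) <- 0
  if (k == 2) {
    chain <- ids
  } else {
    start <- which(lod == max(lod), arr.ind = TRUE)[1, ]
    chain <- ids[start]
    left <- setdiff(ids, chain)
    while (length(left) > 0) {
      d_head <- rf[left, chain[1], drop = TRUE]
      d_tail <- rf[left, chain[length(chain)], drop = TRUE]
      if (min(d_head) <= min(d_tail)) {
        b <- left[which.min(d_head)]
        chain <- c(b, chain)
      } else {
        b <- left[which.min(d_tail)]
        chain <- c(chain, b)
      }
      left <- setdiff(left, b)
    }
    chain <- two_opt(chain, rf)
  }
  adj <- rf[cbind(head(chain, -1), tail(chain, -1))]
  adj <- pmin(adj, 0.4999)  # guard the Kosambi pole for unlinked neighbours
  data.frame(bin_id = chain, position = c(0, cumsum(kosambi(adj))),
             stringsAsFactors = FALSE)
}

two_opt <- function(chain, rf, max_sweeps = 25) {
  path_len <- function(ch) sum(rf[cbind(head(ch, -1), tail(ch, -1))])
  best <- path_len(chain)
  k <- length(chain)
  for (sweep in seq_len(max_sweeps)) {
    improved <- FALSE
    for (i in seq_len(k - 1)) {
      for (j in seq(i + 1, k)) {
        cand <- chain
        cand[i:j] <- rev(cand[i:j])
        len <- path_len(cand)
        if (len < best - 1e-12) {
          chain <- cand; best <- len; improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  chain
}

#' Expand an ordered bin map to a per-marker table
#'
#' Joins each mapped bin's member markers back onto the map so that
#' anchor-based synteny analyses can work at marker level; every marker
#' inherits its bin's group, order and position.
#'
#' @param linkage_map Result of [build_linkage_map()].
#' @param bins The `marker_bins` the map was built from.
#' @return data.frame: `group`, `order`, `bin_id`, `position`,
#'   `marker_id`.
#' @export
map_marker_table <- function(linkage_map, bins) {
  map <- linkage_map$map
  if (nrow(map) == 0)
    return(data.frame(group = character(0), order = integer(0),
                      bin_id = character(0), position = numeric(0),
                      marker_id = character(0), stringsAsFactors = FALSE))
  mem <- strsplit(bins$bins$members[match(map$bin_id, bins$bins$bin_id)],
                  ",", fixed = TRUE)
  n <- lengths(mem)
  data.frame(group = rep(map$group, n), order = rep(map$order, n),
             bin_id = rep(map$bin_id, n), position = rep(map$position, n),
             marker_id = unlist(mem), stringsAsFactors = FALSE)
}

#' Kosambi mapping function and inverse
#'
#' `kosambi(r) = 25 ln((1 + 2r) / (1 - 2r))` centimorgans, accounting for
#' crossover interference; defined for `0 <= r < 0.5`.
#'
#' @param r Recombination fraction(s) in `[0, 0.5)`.
#' @param d Map distance(s) in cM.
#' @return Map distance in cM / recombination fraction.
#' @examples
#' kosambi(0.2)            # 21.18 cM
#' kosambi_inv(kosambi(0.3))
#' @export
kosambi <- function(r) {
  if (any(r < 0 | r >= 0.5))
    stop("`r` must lie in [0, 0.5)", call. = FALSE)
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' @rdname kosambi
#' @export
kosambi_inv <- function(d) {
  if (any(d < 0)) stop("`d` must be non-negative", call. = FALSE)
  tanh(d / 50) / 2
}

#' Build a complete linkage map from binned markers
#'
#' Runs [linkage_pairs()], [group_bins()] and [order_group()] over a bin
#' consensus matrix and returns ordered maps plus a per-group summary.
#' Groups with fewer than 2 bins are reported in the summary but carry no
#' order.
#'
#' @param bins A `marker_bins` object from [build_bins()].
#' @inheritParams group_bins
#' @inheritParams pairwise_linkage
#' @return list: `map` (data.frame `group`, `order`, `bin_id`,
#'   `position`, `representative`, `n_markers`), `groups` (membership),
#'   `pairs`, `summary` (`group`, `n_bins`, `n_markers`, `length_cM`).
#' @export
build_linkage_map <- function(bins, lod_cutoff = 6, rescue_cutoff = 4,
                              min_shared = 10) {
  stopifnot(inherits(bins, "marker_bins"))
  cons <- bins$consensus
  pairs <- linkage_pairs(cons, min_shared = min_shared)
  groups <- group_bins(pairs, rownames(cons), lod_cutoff = lod_cutoff,
                       rescue_cutoff = rescue_cutoff)
  maps <- list()
  for (gid in sort(unique(groups$group[!is.na(groups$group)]))) {
    ids <- groups$bin_id[!is.na(groups$group) & groups$group == gid]
    om <- order_group(ids, pairs)
    om$group <- gid
    om$order <- seq_len(nrow(om))
    maps[[gid]] <- om
  }
  map <- if (length(maps)) do.call(rbind, maps) else
    data.frame(bin_id = character(0), position = numeric(0),
               group = character(0), order = integer(0))
  rownames(map) <- NULL
  bi <- match(map$bin_id, bins$bins$bin_id)
  map$representative <- bins$bins$representative[bi]
  map$n_markers <- bins$bins$n_markers[bi]
  map <- map[, c("group", "order", "bin_id", "position", "representative",
                 "n_markers")]
  summary <- if (nrow(map)) {
    agg <- split(map, map$group)
    data.frame(group = names(agg),
               n_bins = vapply(agg, nrow, integer(1)),
               n_markers = vapply(agg, function(x) sum(x$n_markers),
                                  numeric(1)),
               length_cM = vapply(agg, function(x) max(x$position),
                                  numeric(1)),
               row.names = NULL, stringsAsFactors = FALSE)
  } else data.frame(group = character(0), n_bins = integer(0),
                    n_markers = numeric(0), length_cM = numeric(0))
  list(map = map, groups = groups, pairs = pairs, summary = summary)
}
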