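#' Assign linkage groups to homologous groups by anchor majority
#'
#' Each mapped marker is anchored to a chromosome of the diploid reference
#' through its gene model.  A linkage group's homologous group (HG) is the
#' reference chromosome carrying the majority of its anchored markers;
#' markers anchored there are "congruous".  Anchors on unplaced scaffolds
#' (chromosome `"other"`) count toward totals but never toward the
#' majority, congruous counts, or events.  Ties break toward the
#' chromosome with the longest run of consecutive map-adjacent markers,
#' then the lowest chromosome id (and are flagged).
#'
#' @param map_markers data.frame with one row per mapped marker: `group`,
#'   `order` (map order within the group), `marker_id`.
#' @param anchors data.frame `marker_id`, `chrom` (and optionally
#'   `start`).
#' @return data.frame per group: `group`, `chrom` (majority), `congruous`,
#'   `total`, `congruous_frac`, `tie`.
#' @export
assign_hg <- function(map_markers, anchors) {
  stopifnot(all(c("group", "marker_id") %in% names(map_markers)))
  chrom <- anchors$chrom[match(map_markers$marker_id, anchors$marker_id)]
  out <- lapply(split(seq_len(nrow(map_markers)), map_markers$group),
                function(i) {
    ch <- chrom[i]
    anchored <- !is.na(ch)
    real <- anchored & ch != "other"
    if (!any(real))
      return(data.frame(chrom = NA_character_, congruous = 0L,
                        total = sum(anchored), congruous_frac = NA_real_,
                        tie = FALSE, stringsAsFactors = FALSE))
    tab <- table(ch[real])
    top <- names(tab)[tab == max(tab)]
    tie <- length(top) > 1
    if (tie) {
      ord <- map_markers$order[i]
      runs <- vapply(top, function(cc)
        longest_run(ch[order(ord)] == cc), integer(1))
      top <- top[runs == max(runs)]
      top <- sort(top)[1]
    }
    data.frame(chrom = top[1], congruous = as.integer(tab[[top[1]]]),
               total = sum(anchored),
               congruous_frac = unname(tab[[top[1]]] / sum(anchored)),
               tie = tie, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  cbind(data.frame(group = names(out), stringsAsFactors = FALSE), res,
        row.names = NULL)
}

longest_run <- function(x) {
  x[is.na(x)] <- FALSE
  if (!any(x)) return(0L)
  r <- rle(x)
  max(r$lengths[r$values])
}

#' Summarise congruous-loci fractions across a map
#'
#' The overall fraction is the marker-weighted mean of per-group
#' fractions: total congruous anchored markers over total anchored
#' markers, as a percentage.
#'
#' @param hg Output of [assign_hg()] (one or more maps row-bound).
#' @return list: `per_group` (the input with percentages), `congruous`,
#'   `total`, `percent`.
#' @examples
#' congruous_percent(2798, 3078)  # 90.9
#' @export
congruous_summary <- function(hg) {
  list(per_group = transform(hg, percent = 100 * congruous_frac),
       congruous = sum(hg$congruous), total = sum(hg$total),
       percent = congruous_percent(sum(hg$congruous), sum(hg$total)))
}

#' @rdname congruous_summary
#' @param congruous,total Marker counts.
#' @export
congruous_percent <- function(congruous, total) {
  100 * congruous / total
}

#' Detect interchromosomal rearrangements in a linkage group
#'
#' A linkage group whose majority chromosome is X but which carries at
#' least `min_support` markers anchored to another chromosome Y witnesses
#' an interchromosomal rearrangement between X and Y.  One event is
#' reported per qualifying foreign chromosome; `"other"` anchors never
#' form events.
#'
#' @inheritParams assign_hg
#' @param hg Output of [assign_hg()] for the same map.
#' @param min_support Minimum foreign-marker support (default 3).
#' @return data.frame: `group`, `majority`, `foreign`, `support`,
#'   `marker_ids` (comma-joined).
#' @export
detect_events <- function(map_markers, anchors, hg, min_support = 3) {
  chrom <- anchors$chrom[match(map_markers$marker_id, anchors$marker_id)]
  ev <- list()
  for (g in hg$group[!is.na(hg$chrom)]) {
    maj <- hg$chrom[hg$group == g]
    i <- which(map_markers$group == g & !is.na(chrom) &
                 chrom != maj & chrom != "other")
    if (length(i) == 0) next
    tab <- table(chrom[i])
    for (fc in names(tab)[tab >= min_support]) {
      ev[[length(ev) + 1]] <- data.frame(
        group = g, majority = maj, foreign = fc,
        support = as.integer(tab[[fc]]),
        marker_ids = paste(map_markers$marker_id[i][chrom[i] == fc],
                           collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (length(ev) == 0)
    return(data.frame(group = character(0), majority = character(0),
                      foreign = character(0), support = integer(0),
                      marker_ids = character(0), stringsAsFactors = FALSE))
  do.call(rbind, ev)
}

#' Intersect rearrangement events between two species' maps
#'
#' Events are matched by their unordered chromosome pair
#' \{majority, foreign\}: a pair seen in both species marks a
#' rearrangement predating the speciation.  Each species' events are
#' listed at linkage-group level (several groups may witness one pair),
#' but pairs are de-duplicated within a species for matching; the shared
#' percentage is the number of events (both species combined) whose pair
#' is shared, over all events.
#'
#' @param events_a,events_b Outputs of [detect_events()] for two maps over
#'   the same reference.
#' @return list: `n_events_a`, `n_events_b`, `shared_pairs` (character
#'   vector `"chrA|chrB"`), `n_shared_a`, `n_shared_b`, `n_shared`,
#'   `percent_shared`.
#' @examples
#' # the bookkeeping on printed counts: 24 shared of 53 + 18 -> 33.8%
#' shared_percent(24, 53 + 18)
#' @export
shared_events <- function(events_a, events_b) {
  key <- function(e) {
    if (nrow(e) == 0) return(character(0))
    paste(pmin(e$majority, e$foreign), pmax(e$majority, e$foreign),
          sep = "|")
  }
  ka <- key(events_a); kb <- key(events_b)
  shared <- intersect(unique(ka), unique(kb))
  n_shared_a <- sum(ka %in% shared)
  n_shared_b <- sum(kb %in% shared)
  total <- length(ka) + length(kb)
  list(n_events_a = length(ka), n_events_b = length(kb),
       shared_pairs = sort(shared),
       n_shared_a = n_shared_a, n_shared_b = n_shared_b,
       n_shared = n_shared_a + n_shared_b,
       percent_shared = if (total > 0)
         shared_percent(n_shared_a + n_shared_b, total) else NA_real_)
}

#' @rdname shared_events
#' @param n_shared,n_total Event counts.
#' @export
shared_percent <- function(n_shared, n_total) {
  100 * n_shared / n_total
}

#' Rank collinearity of a linkage group against its reference chromosome
#'
#' Spearman correlation between map order and reference position of the
#' group's congruous markers; |rho| near 1 indicates collinearity and the
#' sign gives the orientation.  Groups with fewer than `min_markers`
#' congruous anchored markers are not scored.
#'
#' @inheritParams detect_events
#' @param min_markers Minimum congruous markers (default 5, the
#'   significant-synteny rule).
#' @return data.frame: `group`, `n`, `rho` (`NA` below the minimum).
#' @export
collinearity_stats <- function(map_markers, anchors, hg, min_markers = 5) {
  j <- match(map_markers$marker_id, anchors$marker_id)
  chrom <- anchors$chrom[j]
  pos <- anchors$start[j]
  out <- lapply(split(seq_len(nrow(map_markers)), map_markers$group),
                function(i) {
    g <- map_markers$group[i[1]]
    maj <- hg$chrom[hg$group == g]
    keep <- i[!is.na(chrom[i]) & chrom[i] == maj]
    if (length(keep) < min_markers)
      return(data.frame(n = length(keep), rho = NA_real_))
    data.frame(n = length(keep),
               rho = suppressWarnings(
                 stats::cor(map_markers$order[keep], pos[keep],
                            method = "spearman")))
  })
  cbind(data.frame(group = names(out), stringsAsFactors = FALSE),
        do.call(rbind, out), row.names = NULL)
}
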