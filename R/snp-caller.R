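#' Screen merged progeny counts for single-dose SNP candidates
#'
#' At a single-dose site the pooled minor:major allele odds across a
#' transmission-balanced F1 pool are 1:15 (see [pooled_minor_fraction()]).
#' Allowing for depth variation and expression bias, sites are kept when
#' the minor/major count ratio of the merged column falls inside the
#' inclusive window (default 1:30 to 1:6).  Sites below the minimum merged
#' depth (default 72, from `min_depth(1/16, 0.99)`) are not screened, and
#' sites where third-allele reads exceed `third_frac` of the filtered
#' depth are rejected as multi-allelic.
#'
#' @param merged A merged-count data.frame from [merge_columns()].
#' @param window Inclusive `c(lo, hi)` bounds on minor/major (default
#'   `c(1/30, 1/6)`).
#' @param min_merged_depth Minimum filtered merged depth.
#' @param third_frac Maximum tolerated third-allele fraction of depth.
#' @return data.frame of candidates: `seqname`, `pos`, `ref`, `major`,
#'   `minor`, `major_n`, `minor_n`, `ratio`.
#' @export
screen_single_dose <- function(merged, window = c(1 / 30, 1 / 6),
                               min_merged_depth = 72, third_frac = 0.01) {
  cnt <- as.matrix(merged[, DNA_BASES4, drop = FALSE])
  depth <- rowSums(cnt)
  ord <- t(apply(cnt, 1, order, decreasing = TRUE))
  major_n <- cnt[cbind(seq_len(nrow(cnt)), ord[, 1])]
  minor_n <- cnt[cbind(seq_len(nrow(cnt)), ord[, 2])]
  ratio <- ifelse(major_n > 0, minor_n / major_n, NA_real_)
  third <- depth - major_n - minor_n
  keep <- depth >= min_merged_depth & minor_n > 0 &
    ratio >= window[1] & ratio <= window[2] &
    third <= third_frac * depth
  keep[is.na(keep)] <- FALSE
  out <- data.frame(
    seqname = merged$seqname, pos = merged$pos, ref = merged$ref,
    major = DNA_BASES4[ord[, 1]], minor = DNA_BASES4[ord[, 2]],
    major_n = major_n, minor_n = minor_n, ratio = ratio,
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign the parent of origin of a single-dose candidate
#'
#' The informative parent of a pseudo-testcross marker is the one that is
#' itself heterozygous: its own minor/major ratio for the candidate allele
#' pair must fall inside the screening window while the other parent shows
#' a minor-allele fraction at or below the error threshold.  If both or
#' neither parent qualifies (or a parent lacks coverage), the candidate is
#' `"ambiguous"` and excluded from mapping.
#'
#' @param cand Candidate data.frame from [screen_single_dose()].
#' @param p1,p2 Parent pileup data.frames from [read_pileup()].
#' @param window Inclusive ratio window applied to the qualifying parent.
#' @param err_frac Maximum minor-allele read fraction in the other parent.
#' @param min_cov Coverage prefilter applied to both parents.
#' @return Character vector over candidates: `"P1"`, `"P2"`, `"ambiguous"`.
#' @export
assign_parent <- function(cand, p1, p2, window = c(1 / 30, 1 / 6),
                          err_frac = 0.01, min_cov = 7) {
  stat <- function(p) {
    j <- match(paste(cand$seqname, cand$pos), paste(p$seqname, p$pos))
    cnt <- as.matrix(p[, DNA_BASES4, drop = FALSE])
    maj <- minor <- rep(NA_real_, nrow(cand))
    has <- !is.na(j)
    maj[has] <- cnt[cbind(j[has], match(cand$major[has], DNA_BASES4))]
    minor[has] <- cnt[cbind(j[has], match(cand$minor[has], DNA_BASES4))]
    depth <- rep(NA_real_, nrow(cand))
    depth[has] <- rowSums(cnt[j[has], , drop = FALSE])
    list(maj = maj, minor = minor, depth = depth)
  }
  s1 <- stat(p1); s2 <- stat(p2)
  qual <- function(s) {
    r <- ifelse(s$maj > 0, s$minor / s$maj, NA_real_)
    !is.na(s$depth) & s$depth > min_cov &
      !is.na(r) & r >= window[1] & r <= window[2]
  }
  clean <- function(s) {
    fr <- ifelse(s$depth > 0, s$minor / s$depth, NA_real_)
    !is.na(s$depth) & s$depth > min_cov & !is.na(fr) & fr <= err_frac
  }
  q1 <- qual(s1); q2 <- qual(s2)
  c1 <- clean(s1); c2 <- clean(s2)
  out <- rep("ambiguous", nrow(cand))
  out[q1 & c2 & !q2] <- "P1"
  out[q2 & c1 & !q1] <- "P2"
  out
}

#' Call per-progeny presence/absence of a candidate allele
#'
#' A progeny is *present* where at least `min_minor_reads`
#' quality-filtered minor-allele reads are seen (default 2, guarding
#' against lone sequencing errors).  An *absence* call additionally
#' requires enough depth that a single-dose allele (sampling probability
#' 1/8 within one octoploid individual) would almost surely have been
#' seen: `min_absence_depth` defaults to 22 reads, i.e.
#' `min_depth(1/8, 0.95)`.  Samples failing the coverage prefilter, or
#' too shallow to support an absence call, are *missing*.
#'
#' @inheritParams assign_parent
#' @param columns Named list of progeny pileup data.frames.
#' @param min_minor_reads Presence threshold on minor-read count.
#' @param min_cov Coverage prefilter.
#' @param min_absence_depth Minimum filtered depth for an absence call.
#' @return Integer matrix (candidates x progeny): 1 presence, 0 absence,
#'   NA missing.
#' @export
genotype_progeny <- function(cand, columns, min_minor_reads = 2,
                             min_cov = 7, min_absence_depth = 22) {
  key <- paste(cand$seqname, cand$pos)
  g <- matrix(NA_integer_, nrow(cand), length(columns),
              dimnames = list(cand$seqname, names(columns)))
  for (i in seq_along(columns)) {
    p <- columns[[i]]
    j <- match(key, paste(p$seqname, p$pos))
    has <- !is.na(j)
    cnt <- as.matrix(p[, DNA_BASES4, drop = FALSE])
    depth <- rowSums(cnt)[j[has]]
    minor <- cnt[cbind(j[has], match(cand$minor[has], DNA_BASES4))]
    pres <- depth > min_cov & minor >= min_minor_reads
    absent <- depth >= min_absence_depth & minor < min_minor_reads
    g[has, i] <- ifelse(pres, 1L, ifelse(absent, 0L, NA_integer_))
  }
  rownames(g) <- paste0(cand$seqname, ":", cand$pos)
  g
}

#' Full single-dose SNP calling pass over a sample sheet
#'
#' Reads every pileup, merges the progeny columns, screens single-dose
#' candidates by the ratio window, assigns each candidate's parent of
#' origin and calls per-progeny presence/absence.
#'
#' @param samples data.frame with `sample_id`, `role` (one of `parent1`,
#'   `parent2`, `progeny`) and `path` columns, as written by
#'   [simulate_cross()].
#' @param min_base_quality Phred filter for [read_pileup()].
#' @inheritParams screen_single_dose
#' @inheritParams genotype_progeny
#' @param err_frac Error threshold for [assign_parent()].
#' @return A list: `markers` (candidate table plus `parent` and
#'   `marker_id`), `genotypes` (matrix markers x progeny), `merged`
#'   (merged counts).
#' @export
call_single_dose <- function(samples, min_base_quality = 28,
                             window = c(1 / 30, 1 / 6),
                             min_merged_depth = 72, third_frac = 0.01,
                             min_minor_reads = 2, min_cov = 7,
                             min_absence_depth = 22, err_frac = 0.01) {
  stopifnot(all(c("sample_id", "role", "path") %in% names(samples)),
            sum(samples$role == "parent1") == 1,
            sum(samples$role == "parent2") == 1)
  cols <- lapply(samples$path, read_pileup,
                 min_base_quality = min_base_quality)
  names(cols) <- samples$sample_id
  prog <- cols[samples$role == "progeny"]
  merged <- merge_columns(prog)
  cand <- screen_single_dose(merged, window = window,
                             min_merged_depth = min_merged_depth,
                             third_frac = third_frac)
  parent <- assign_parent(cand, cols[[which(samples$role == "parent1")]],
                          cols[[which(samples$role == "parent2")]],
                          window = window, err_frac = err_frac,
                          min_cov = min_cov)
  geno <- genotype_progeny(cand, prog, min_minor_reads = min_minor_reads,
                           min_cov = min_cov,
                           min_absence_depth = min_absence_depth)
  cand$parent <- parent
  cand$marker_id <- paste0(cand$seqname, ":", cand$pos)
  list(markers = cand, genotypes = geno, merged = merged)
}
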