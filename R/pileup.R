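#' Parse an mpileup-dialect text file into per-site base counts
#'
#' Consumes the 6-column dialect written by [simulate_pileups()] (and by
#' `samtools mpileup` restricted to substitution calls): sequence name,
#' 1-based position, reference base, depth, read bases, base qualities.
#' `.`/`,` resolve to the reference base; `ACGT`/`acgt` are counted
#' case-folded; read-start (`^` + mapping quality) and read-end (`$`)
#' markers are tolerated and stripped; any other character is a parse
#' error reported with its line number.  Bases with Phred quality less
#' than or equal to `min_base_quality` are excluded from the counts.
#'
#' @param path File path (or connection readable by [readLines()]).
#' @param min_base_quality Phred threshold; only strictly greater
#'   qualities are counted (default 28).
#' @return A data.frame with one row per pileup line: `seqname`, `pos`,
#'   `ref`, filtered counts `A`, `C`, `G`, `T`, and `raw_depth`.
#' @export
read_pileup <- function(path, min_base_quality = 28) {
  lines <- readLines(path)
  empty <- data.frame(seqname = character(0), pos = integer(0),
                      ref = character(0), A = integer(0), C = integer(0),
                      G = integer(0), T = integer(0), raw_depth = integer(0),
                      stringsAsFactors = FALSE)
  if (length(lines) == 0) return(empty)
  f <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 6))
    stop("malformed pileup line ", which(nf < 6)[1], ": expected 6 columns",
         call. = FALSE)
  f <- do.call(rbind, lapply(f, `[`, 1:6))
  bases <- gsub("\\^.", "", f[, 5])
  bases <- gsub("$", "", bases, fixed = TRUE)
  quals <- f[, 6]
  nb <- nchar(bases)
  if (any(nb != nchar(quals)))
    stop("malformed pileup line ", which(nb != nchar(quals))[1],
         ": base and quality strings differ in length", call. = FALSE)
  n <- length(lines)
  refs <- toupper(f[, 3])

  # one pass over the concatenated base/quality strings
  bcode <- utf8ToInt(paste(bases, collapse = ""))
  qcode <- utf8ToInt(paste(quals, collapse = "")) - 33L
  line_of <- rep.int(seq_len(n), nb)
  cls <- BASE_CLASS[bcode + 1L]
  if (anyNA(cls)) {
    bad <- line_of[which(is.na(cls))[1]]
    stop("malformed pileup line ", bad, ": unexpected character in bases",
         call. = FALSE)
  }
  ref_cls <- match(refs, DNA_BASES4)[line_of]
  cls <- ifelse(cls == 5L, ref_cls, cls)  # '.'/',' -> reference base
  ok <- qcode > min_base_quality & !is.na(cls) & cls <= 4L
  counts <- matrix(0L, n, 4, dimnames = list(NULL, DNA_BASES4))
  if (any(ok)) {
    tab <- tabulate((line_of[ok] - 1L) * 4L + cls[ok], nbins = n * 4L)
    counts <- matrix(tab, n, 4, byrow = TRUE, dimnames = list(NULL, DNA_BASES4))
  }
  data.frame(seqname = f[, 1], pos = as.integer(f[, 2]), ref = refs,
             counts, raw_depth = as.integer(f[, 4]),
             stringsAsFactors = FALSE)
}

# character-code lookup: A/C/G/T (case-folded) -> 1..4, './,' -> 5 (ref),
# 'N'/'n'/'*' -> NA-able sentinel 6 (ignored), anything else NA (error).
BASE_CLASS <- local({
  v <- rep(NA_integer_, 256)
  set <- function(ch, val) v[utf8ToInt(ch) + 1L] <<- val
  set("A", 1L); set("a", 1L); set("C", 2L); set("c", 2L)
  set("G", 3L); set("g", 3L); set("T", 4L); set("t", 4L)
  set(".", 5L); set(",", 5L)
  set("N", 6L); set("n", 6L); set("*", 6L)
  v
})

#' Per-sample coverage prefilter
#'
#' A sample is considered genotypable at a site only when its
#' quality-filtered depth exceeds `min_cov` reads (default 7, i.e. the
#' "coverage > 7" rule); failing samples are treated as missing there.
#'
#' @param counts A matrix/data.frame with columns `A`,`C`,`G`,`T`, or a
#'   numeric vector of 4 counts.
#' @param min_cov Strict lower bound on filtered depth.
#' @return Logical vector, `TRUE` where the site passes for the sample.
#' @export
prefilter <- function(counts, min_cov = 7) {
  filtered_depth(counts) > min_cov
}

filtered_depth <- function(counts) {
  if (is.null(dim(counts))) sum(counts[DNA_BASES4])
  else rowSums(as.matrix(counts[, DNA_BASES4, drop = FALSE]))
}

#' Merge per-progeny pileup columns
#'
#' Sums quality-filtered base counts across progeny at every locus seen in
#' any sample (absent samples contribute zero), and records how many
#' progeny had nonzero raw depth.  Merging is exactly additive.
#'
#' @param columns A list of data.frames from [read_pileup()].
#' @return data.frame: `seqname`, `pos`, `ref`, summed `A`,`C`,`G`,`T`,
#'   and `n_covered`.
#' @export
merge_columns <- function(columns) {
  stopifnot(length(columns) > 0)
  keys <- lapply(columns, function(x) paste(x$seqname, x$pos, sep = "\r"))
  all_keys <- unique(unlist(keys))
  n <- length(all_keys)
  acc <- matrix(0L, n, 4, dimnames = list(NULL, DNA_BASES4))
  covered <- integer(n)
  meta <- NULL
  for (i in seq_along(columns)) {
    x <- columns[[i]]
    j <- match(keys[[i]], all_keys)
    acc[j, ] <- acc[j, ] + as.matrix(x[, DNA_BASES4])
    covered[j] <- covered[j] + (x$raw_depth > 0)
    if (is.null(meta)) {
      meta <- data.frame(seqname = rep(NA_character_, n), pos = NA_integer_,
                         ref = NA_character_, stringsAsFactors = FALSE)
    }
    meta$seqname[j] <- x$seqname
    meta$pos[j] <- x$pos
    meta$ref[j] <- x$ref
  }
  cbind(meta, as.data.frame(acc), n_covered = covered)
}
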