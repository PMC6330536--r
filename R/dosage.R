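#' Segregation and detection combinatorics for autopolyploid dosage classes
#'
#' In an autopolyploid with `ploidy` homologous chromosomes (an even number
#' 2m), meiosis under pure random chromosome segregation draws `ploidy/2`
#' homologs into each gamete.  An allele present in `dose` copies in one
#' parent (and absent from the other) is then transmitted hypergeometrically,
#' giving the classical simplex/duplex/triplex/quadruplex ratios: for an
#' octoploid these are absence fractions 1/2, 3/14, 1/14 and 1/70 for doses
#' 1 to 4.
#'
#' All probabilities are ratios of binomial coefficients over small integers,
#' which [choose()] evaluates exactly in double precision, so the returned
#' values are exact.
#'
#' @param dose Integer number of copies of the (minor) allele carried by the
#'   heterozygous parent, between 0 and `ploidy`.
#' @param ploidy Even integer number of homologous chromosomes (2m); 8 for an
#'   octoploid.
#' @return `gamete_absence_prob()`: probability that a gamete carries zero
#'   copies of the allele.  `f1_presence_fraction()`: expected fraction of F1
#'   progeny carrying at least one copy when the other parent is nulliplex.
#' @examples
#' gamete_absence_prob(1, 8)          # 1/2: simplex markers segregate 1:1
#' gamete_absence_prob(2, 8)          # 3/14 (duplex)
#' f1_presence_fraction(4, 8)         # 69/70 (quadruplex, nearly fixed)
#' @export
gamete_absence_prob <- function(dose, ploidy = 8) {
  check_ploidy(ploidy)
  check_dose(dose, ploidy)
  m <- ploidy / 2L
  choose(ploidy - dose, m) / choose(ploidy, m)
}

#' @rdname gamete_absence_prob
#' @export
f1_presence_fraction <- function(dose, ploidy = 8) {
  1 - gamete_absence_prob(dose, ploidy)
}

#' Expected pooled minor-allele read fraction across a cross
#'
#' When sequencing reads are drawn uniformly from both parents' haplotypes
#' (e.g. the merged, transmission-balanced F1 pool), a site where the parents
#' carry the minor allele in `dose_p1` and `dose_p2` copies has expected
#' minor-allele read fraction `(dose_p1 + dose_p2) / (2 * ploidy)`.  For a
#' single-dose site in one octoploid parent this is 1/16, i.e. minor:major
#' odds of 1:15.
#'
#' @param dose_p1,dose_p2 Minor-allele dose in each parent (0..`ploidy`).
#' @inheritParams gamete_absence_prob
#' @return Expected minor-allele fraction among pooled reads.
#' @examples
#' pooled_minor_fraction(1, 0, 8)   # 1/16, odds 1:15
#' @export
pooled_minor_fraction <- function(dose_p1, dose_p2, ploidy = 8) {
  check_ploidy(ploidy)
  check_dose(dose_p1, ploidy)
  check_dose(dose_p2, ploidy)
  (dose_p1 + dose_p2) / (2 * ploidy)
}

#' Probability of sampling a minor allele at least once, and the depth
#' required to do so
#'
#' With per-read probability `p` of sampling the minor allele, the chance of
#' seeing it at least once among `n` reads is `1 - (1 - p)^n`.
#' `min_depth()` inverts this: the smallest integer depth at which that
#' probability reaches `certainty`.  For a single-dose allele pooled across
#' an octoploid cross (p = 1/16), 72 reads are needed to reach 99%.
#'
#' @param p Per-read probability of sampling the minor allele, in (0, 1).
#' @param n Non-negative integer read depth.
#' @param certainty Target detection probability, in (0, 1).
#' @return `detection_prob()`: a probability. `min_depth()`: an integer depth.
#' @examples
#' detection_prob(1 / 16, 72)   # ~0.99
#' min_depth(1 / 16, 0.99)      # 72
#' @export
detection_prob <- function(p, n) {
  if (!is.numeric(p) || any(p <= 0) || any(p >= 1))
    stop("`p` must lie strictly between 0 and 1", call. = FALSE)
  if (!is.numeric(n) || any(n < 0) || any(n != floor(n)))
    stop("`n` must be a non-negative integer depth", call. = FALSE)
  1 - (1 - p)^n
}

#' @rdname detection_prob
#' @export
min_depth <- function(p, certainty) {
  if (!is.numeric(p) || any(p <= 0) || any(p >= 1))
    stop("`p` must lie strictly between 0 and 1", call. = FALSE)
  if (!is.numeric(certainty) || any(certainty <= 0) || any(certainty >= 1))
    stop("`certainty` must lie strictly between 0 and 1", call. = FALSE)
  n <- ceiling(log(1 - certainty) / log(1 - p))
  # guard against floating-point landing one off the true boundary
  n <- mapply(function(ni, pi, ci) {
    while (ni > 0 && detection_prob(pi, ni - 1) >= ci) ni <- ni - 1
    while (detection_prob(pi, ni) < ci) ni <- ni + 1
    ni
  }, n, p, certainty)
  as.integer(n)
}

#' Segregation summary table for all dosage classes
#'
#' One row per dose 0..`ploidy`: the gamete absence fraction, the F1
#' presence:absence odds, and the pooled-read depth needed to detect the
#' allele at each requested certainty (using the pooled minor fraction
#' `dose / (2 * ploidy)` of a cross where the other parent is nulliplex).
#'
#' @inheritParams gamete_absence_prob
#' @param certainties Detection certainties to tabulate depths for.
#' @return A data.frame with columns `dose`, `absence_fraction`,
#'   `presence`, `absence` (integer odds) and one `min_depth_*` column per
#'   certainty (NA for dose 0, which has nothing to detect).
#' @export
dosage_table <- function(ploidy = 8, certainties = c(0.95, 0.99)) {
  check_ploidy(ploidy)
  dose <- 0:ploidy
  absf <- vapply(dose, gamete_absence_prob, numeric(1), ploidy = ploidy)
  # integer odds from the exact hypergeometric denominator C(ploidy, m)
  denom <- choose(ploidy, ploidy / 2)
  abs_n <- round(absf * denom)
  g <- mapply(function(a, b) if (a == 0 && b == 0) 1 else gcd_int(a, b),
              denom - abs_n, abs_n)
  out <- data.frame(
    dose = dose,
    absence_fraction = absf,
    presence = (denom - abs_n) / g,
    absence = abs_n / g
  )
  for (ct in certainties) {
    pf <- dose / (2 * ploidy)
    d <- rep(NA_integer_, length(dose))
    ok <- pf > 0 & pf < 1
    d[ok] <- min_depth(pf[ok], ct)
    out[[sprintf("min_depth_%g", ct)]] <- d
  }
  out
}

check_ploidy <- function(ploidy) {
  if (length(ploidy) != 1 || !is.numeric(ploidy) || ploidy < 2 ||
      ploidy != floor(ploidy) || ploidy %% 2 != 0)
    stop("`ploidy` must be an even integer >= 2", call. = FALSE)
  invisible(ploidy)
}

check_dose <- function(dose, ploidy) {
  if (!is.numeric(dose) || any(dose != floor(dose)) ||
      any(dose < 0) || any(dose > ploidy))
    stop("`dose` must be an integer in 0..ploidy", call. = FALSE)
  invisible(dose)
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)
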