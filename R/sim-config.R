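#' Configuration for the synthetic octoploid F1 cross simulator
#'
#' Bundles every tunable of the simulator with defaults chosen to emulate an
#' RNA-seq pseudo-testcross between two octoploid parents sharing a
#' 10-chromosome diploid reference gene space: 59 progeny, a dosage mixture
#' of 70/20/7/3% for simplex..quadruplex variant sites, gene-level
#' negative-binomial sequencing depth, and Phred-scaled base-call error.
#'
#' @param seed Integer seed; every simulator stage derives its RNG stream
#'   from it, so a config fully determines the dataset.
#' @param n_progeny Number of F1 individuals (default 59).
#' @param ploidy Even number of homologs per parent (default 8).
#' @param dosage_mix Probabilities of doses 1..4 for a new variant site;
#'   must sum to 1. Default `c(0.70, 0.20, 0.07, 0.03)`.
#' @param n_chrom Number of reference chromosomes (default 10).
#' @param n_genes Total genes across the reference (default 200).
#' @param gene_len_range Range of CDS lengths in codons (default 100..200,
#'   i.e. 300-600 bp).
#' @param intergenic_bp Fixed intergenic gap used when laying genes out on a
#'   chromosome (default 2000 bp).
#' @param snp_rate Per-bp probability that a CDS position carries a parental
#'   variant site (default 0.012, in line with the high SNP density of
#'   heterozygous polyploid transcriptomes).
#' @param mean_depth Mean per-gene read depth per individual (default 40).
#' @param expr_sdlog Lognormal sd (log scale) of the per-gene expression
#'   level shared by all individuals (default 0.25); gene-to-gene
#'   expression differences hit every library alike, which is what drives
#'   whole-marker dropout in RNA-seq maps.
#' @param depth_dispersion Negative-binomial size parameter for the
#'   individual-level depth noise around a gene's expression level
#'   (default 60, i.e. a depth CV of roughly 25% for a gene at the mean,
#'   as for same-tissue libraries of matched size; smaller = more
#'   overdispersed).
#' @param base_error Per-read probability that the reported base is replaced
#'   by a uniformly drawn base (default 0.002).
#' @param qual_levels,qual_probs Discrete Phred quality distribution for
#'   individual base calls (encoded Phred+33 in pileups).
#' @param chrom_cM Genetic length of each chromosome in centimorgans
#'   (recycled across chromosomes; default 100).
#' @param expressed_frac Fraction of genes expressed in the sampled tissue;
#'   unexpressed genes yield no reads in any individual (default 0.95).
#' @param parent_depth_mean Mean per-gene depth for the two parental
#'   libraries (defaults to `mean_depth`).
#' @param hap_expr_weights Optional length-`ploidy` vector of per-haplotype
#'   expression weights (homolog expression dominance); default uniform.
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(seed = 1, n_genes = 50)
#' @export
sim_config <- function(seed,
                       n_progeny = 59,
                       ploidy = 8,
                       dosage_mix = c(0.70, 0.20, 0.07, 0.03),
                       n_chrom = 10,
                       n_genes = 200,
                       gene_len_range = c(100, 200),
                       intergenic_bp = 2000,
                       snp_rate = 0.012,
                       mean_depth = 40,
                       expr_sdlog = 0.25,
                       depth_dispersion = 60,
                       base_error = 0.002,
                       qual_levels = c(25, 32, 37, 40),
                       qual_probs = c(0.06, 0.14, 0.30, 0.50),
                       chrom_cM = 100,
                       expressed_frac = 0.95,
                       parent_depth_mean = mean_depth,
                       hap_expr_weights = NULL) {
  stopifnot(length(seed) == 1, is.numeric(seed), seed == floor(seed))
  check_ploidy(ploidy)
  if (n_progeny < 2) stop("`n_progeny` must be >= 2", call. = FALSE)
  if (abs(sum(dosage_mix) - 1) > 1e-8)
    stop("`dosage_mix` must sum to 1", call. = FALSE)
  if (any(dosage_mix < 0) || length(dosage_mix) != 4)
    stop("`dosage_mix` must be 4 non-negative probabilities (doses 1..4)",
         call. = FALSE)
  if (n_genes < n_chrom && n_genes > 0)
    stop("need at least one gene per chromosome", call. = FALSE)
  if (n_genes <= 0) stop("`n_genes` must be positive", call. = FALSE)
  if (length(qual_levels) != length(qual_probs) ||
      abs(sum(qual_probs) - 1) > 1e-8)
    stop("`qual_probs` must match `qual_levels` and sum to 1", call. = FALSE)
  if (base_error < 0 || base_error >= 1)
    stop("`base_error` must be in [0, 1)", call. = FALSE)
  if (!is.null(hap_expr_weights)) {
    if (length(hap_expr_weights) != ploidy || any(hap_expr_weights < 0) ||
        sum(hap_expr_weights) <= 0)
      stop("`hap_expr_weights` must be `ploidy` non-negative weights",
           call. = FALSE)
    hap_expr_weights <- hap_expr_weights / sum(hap_expr_weights)
  }
  cfg <- list(
    seed = as.integer(seed), n_progeny = as.integer(n_progeny),
    ploidy = as.integer(ploidy), dosage_mix = dosage_mix,
    n_chrom = as.integer(n_chrom), n_genes = as.integer(n_genes),
    gene_len_range = gene_len_range, intergenic_bp = intergenic_bp,
    snp_rate = snp_rate, mean_depth = mean_depth, expr_sdlog = expr_sdlog,
    depth_dispersion = depth_dispersion, base_error = base_error,
    qual_levels = qual_levels, qual_probs = qual_probs,
    chrom_cM = rep_len(chrom_cM, n_chrom),
    expressed_frac = expressed_frac,
    parent_depth_mean = parent_depth_mean,
    hap_expr_weights = hap_expr_weights
  )
  class(cfg) <- "sim_config"
  cfg
}

# Stage-specific deterministic RNG streams derived from the config seed.
# Offsets are fixed so each stage is reproducible on its own.
sim_seed <- function(cfg, stage) {
  offs <- c(reference = 1L, variants = 2L, meiosis = 3L, pileup = 4L,
            expression = 5L)
  s <- (as.numeric(cfg$seed) * 7L + offs[[stage]]) %% 2147483647
  set.seed(as.integer(s))
  invisible(s)
}
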