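#' Build a synthetic diploid reference gene space
#'
#' Generates `cfg$n_genes` genes laid out without overlap across
#' `cfg$n_chrom` chromosomes (0-based half-open coordinates), each with a
#' random in-frame CDS over A/C/G/T containing no internal stop codons.
#' The reference stands in for the diploid relative's gene models against
#' which RNA-seq reads of the polyploid are aligned and anchored.
#'
#' @param cfg A [sim_config()].
#' @return An object of class `octo_reference`: a list with `chromosomes`
#'   (data.frame: `chrom`, `length`), `genes` (data.frame: `gene_id`,
#'   `chrom`, `start`, `end`, `strand`) and `cds` (named character vector).
#' @export
build_reference <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  sim_seed(cfg, "reference")
  n <- cfg$n_genes
  chrom_names <- sprintf("chr%02d", seq_len(cfg$n_chrom))
  chrom <- chrom_names[rep_len(seq_len(cfg$n_chrom), n)]
  chrom <- sort(chrom)  # contiguous blocks, balanced round-robin counts
  len_codons <- sample(cfg$gene_len_range[1]:cfg$gene_len_range[2], n,
                       replace = TRUE)
  cds <- vapply(len_codons, random_cds, character(1))
  gene_id <- sprintf("g%05d", seq_len(n))
  genes <- data.frame(gene_id = gene_id, chrom = chrom,
                      start = 0L, end = 0L,
                      strand = sample(c("+", "-"), n, replace = TRUE),
                      stringsAsFactors = FALSE)
  ref <- list(genes = genes, cds = setNames(cds, gene_id))
  ref$genes <- layout_genes(ref$genes, nchar(cds), cfg$intergenic_bp)
  ref$chromosomes <- chrom_lengths(ref$genes, cfg$intergenic_bp, chrom_names)
  ref$intergenic_bp <- cfg$intergenic_bp
  class(ref) <- "octo_reference"
  ref
}

# Assign non-overlapping 0-based half-open intervals along each chromosome,
# preserving the row order of `genes` within a chromosome.
layout_genes <- function(genes, widths, gap) {
  for (ch in unique(genes$chrom)) {
    i <- which(genes$chrom == ch)
    w <- widths[i]
    starts <- cumsum(c(0L, head(w + gap, -1)))
    genes$start[i] <- as.integer(starts)
    genes$end[i] <- as.integer(starts + w)
  }
  genes
}

chrom_lengths <- function(genes, gap, chrom_names) {
  len <- vapply(chrom_names, function(ch) {
    e <- genes$end[genes$chrom == ch]
    if (length(e) == 0) as.integer(gap) else as.integer(max(e) + gap)
  }, integer(1))
  data.frame(chrom = chrom_names, length = len, stringsAsFactors = FALSE)
}

# Random in-frame CDS with no internal stop codons.
random_cds <- function(n_codons) {
  paste(sample(NON_STOP_CODONS, n_codons, replace = TRUE), collapse = "")
}

#' Spike parental variant sites into a reference
#'
#' Each site lands in exactly one parent, with a dose drawn from
#' `cfg$dosage_mix` and carrier haplotypes chosen uniformly without
#' replacement among that parent's `ploidy` homologs; the other parent is
#' nulliplex at the site.  Site positions are sampled per gene at
#' `cfg$snp_rate` per CDS bp.
#'
#' @param ref An `octo_reference`.
#' @inheritParams build_reference
#' @return A list with `parent1` and `parent2` (each of class
#'   `octo_parent`: the reference plus that parent's variant table) and
#'   `sites`, the combined truth table with columns `site_id`, `gene_id`,
#'   `offset` (0-based within the CDS), `ref`, `alt`, `parent`, `dose`, and
#'   `carriers` (comma-separated haplotype indices).
#' @export
spike_variants <- function(ref, cfg) {
  stopifnot(inherits(ref, "octo_reference"), inherits(cfg, "sim_config"))
  sim_seed(cfg, "variants")
  ids <- ref$genes$gene_id
  widths <- nchar(ref$cds[ids])
  n_sites <- rbinom(length(ids), widths, cfg$snp_rate)
  gene_id <- rep(ids, n_sites)
  offset <- unlist(lapply(seq_along(ids), function(i) {
    if (n_sites[i] == 0) return(integer(0))
    sort(sample.int(widths[i], n_sites[i]) - 1L)
  }), use.names = FALSE)
  n <- length(gene_id)
  if (n == 0) stop("no variant sites sampled; raise `snp_rate`", call. = FALSE)
  refbase <- substring(ref$cds[gene_id], offset + 1L, offset + 1L)
  alt <- vapply(refbase, function(b) sample(setdiff(DNA_BASES4, b), 1),
                character(1), USE.NAMES = FALSE)
  parent <- sample(c("P1", "P2"), n, replace = TRUE)
  dose <- sample(1:4, n, replace = TRUE, prob = cfg$dosage_mix)
  carriers <- vapply(dose, function(d)
    paste(sort(sample.int(cfg$ploidy, d)), collapse = ","), character(1))
  sites <- data.frame(
    site_id = paste0(gene_id, ":", offset + 1L),
    gene_id = gene_id, offset = offset, ref = refbase, alt = alt,
    parent = parent, dose = dose, carriers = carriers,
    stringsAsFactors = FALSE
  )
  mk_parent <- function(lab) {
    p <- list(ref = ref, variants = sites[sites$parent == lab, , drop = FALSE],
              label = lab, ploidy = cfg$ploidy)
    class(p) <- "octo_parent"
    p
  }
  list(parent1 = mk_parent("P1"), parent2 = mk_parent("P2"), sites = sites)
}
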