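#' Simulate F1 progeny genotypes by autopolyploid meiosis
#'
#' Each meiosis pairs the parent's `ploidy` homologs at random into
#' bivalents (no preferential pairing), recombines each bivalent with a
#' Poisson number of crossovers (mean = chromosome genetic length / 100
#' Morgans, positions uniform), and passes one recombinant product per
#' bivalent to the gamete, i.e. `ploidy/2` chromosomes.  Random bivalent
#' pairing with one product per bivalent reproduces the hypergeometric
#' single-locus segregation of [gamete_absence_prob()] exactly.
#'
#' Variant positions are mapped to centimorgans proportionally to their
#' physical position on the parent's own (possibly rearranged) chromosome.
#'
#' @param parent1,parent2 `octo_parent` objects from [spike_variants()]
#'   (their `$ref` may be replaced by a rearranged species reference).
#' @param cfg The [sim_config()].
#' @return An object of class `octo_truth`: list with `sites` (site
#'   metadata plus the species chromosome and cM position of each site),
#'   `copies` (integer matrix sites x progeny: transmitted minor-allele
#'   copies), `presence` (logical matrix), and `progeny` (ids).
#' @export
simulate_progeny <- function(parent1, parent2, cfg) {
  stopifnot(inherits(parent1, "octo_parent"), inherits(parent2, "octo_parent"),
            inherits(cfg, "sim_config"))
  if (parent1$ploidy != parent2$ploidy)
    stop("parents must share a ploidy", call. = FALSE)
  sim_seed(cfg, "meiosis")
  progeny <- sprintf("F%02d", seq_len(cfg$n_progeny))
  res1 <- meiosis_one_parent(parent1, cfg, progeny)
  res2 <- meiosis_one_parent(parent2, cfg, progeny)
  sites <- rbind(res1$sites, res2$sites)
  copies <- rbind(res1$copies, res2$copies)
  ord <- order(sites$gene_id, sites$offset)
  sites <- sites[ord, , drop = FALSE]
  copies <- copies[ord, , drop = FALSE]
  rownames(sites) <- NULL
  out <- list(sites = sites, copies = copies, presence = copies > 0L,
              progeny = progeny)
  class(out) <- "octo_truth"
  out
}

meiosis_one_parent <- function(parent, cfg, progeny) {
  v <- parent$variants
  ref <- parent$ref
  g <- ref$genes[match(v$gene_id, ref$genes$gene_id), , drop = FALSE]
  chrom_idx <- match(g$chrom, ref$chromosomes$chrom)
  L <- cfg$chrom_cM[chrom_idx]
  pos_cM <- (g$start + v$offset) / ref$chromosomes$length[chrom_idx] * L
  sites <- cbind(v, data.frame(chrom = g$chrom, cM = pos_cM,
                               stringsAsFactors = FALSE))
  carr <- lapply(strsplit(v$carriers, ",", fixed = TRUE), as.integer)
  ploidy <- parent$ploidy
  # carrier membership: sites x homolog
  cmat <- matrix(FALSE, nrow(v), ploidy)
  for (i in seq_along(carr)) cmat[i, carr[[i]]] <- TRUE

  copies <- matrix(0L, nrow(v), length(progeny),
                   dimnames = list(v$site_id, progeny))
  by_chrom <- split(seq_len(nrow(v)), g$chrom)
  for (j in seq_along(progeny)) {
    for (ch in names(by_chrom)) {
      idx <- by_chrom[[ch]]
      copies[idx, j] <- gamete_copies(pos_cM[idx], cmat[idx, , drop = FALSE],
                                      L[idx][1], ploidy)
    }
  }
  list(sites = sites, copies = copies)
}

# One gamete for one chromosome: random bivalent pairing, Poisson crossovers
# per bivalent, one recombinant product per bivalent.  Returns per-site
# transmitted copy counts given site cM positions and carrier membership.
gamete_copies <- function(pos, cmat, len_cM, ploidy) {
  pairing <- matrix(sample.int(ploidy), ncol = 2)
  total <- integer(length(pos))
  for (k in seq_len(nrow(pairing))) {
    h <- pairing[k, ]
    n_xo <- rpois(1, len_cM / 100)
    first <- sample.int(2L, 1L)
    if (n_xo == 0) {
      src <- rep(h[first], length(pos))
    } else {
      breaks <- sort(runif(n_xo, 0, len_cM))
      par <- (findInterval(pos, breaks) + first - 1L) %% 2L + 1L
      src <- h[par]
    }
    total <- total + cmat[cbind(seq_along(pos), src)]
  }
  total
}
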