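#' Write mpileup-dialect files for a simulated cross
#'
#' Emulates RNA-seq of every individual (two parents + progeny).  Each
#' expressed gene has one lognormal expression level shared by all
#' individuals (sdlog `cfg$expr_sdlog`, mean `cfg$mean_depth`, or
#' `cfg$parent_depth_mean` for the parents); each individual then draws a
#' negative-binomial depth around it (size `cfg$depth_dispersion`), and
#' all variant sites of a gene share that individual's depth.
#' At a site carried in `k` of `ploidy` homologs the minor-allele read count
#' is Binomial(depth, k/ploidy) (parental haplotype expression weights, if
#' configured, reweight the parents).  Each read is independently replaced
#' by a uniformly drawn base with probability `cfg$base_error`, and receives
#' a Phred+33 quality drawn from the configured distribution.
#'
#' The dialect written (and consumed by [read_pileup()]) is 6 tab-separated
#' columns: sequence name (the gene id), 1-based position in the CDS,
#' reference base, depth, read bases ('.'/',' for the reference,
#' `ACGT`/`acgt` otherwise), and qualities.  No indels are emitted.
#'
#' @param truth An `octo_truth` from [simulate_progeny()].
#' @param parents The list returned by [spike_variants()] (for parental
#'   genotypes).
#' @param cfg The [sim_config()].
#' @param dir Output directory (created if needed).
#' @param expressed Optional named logical vector over genes; defaults to a
#'   fresh draw at `cfg$expressed_frac`.
#' @return Invisibly, a data.frame sample sheet (`sample_id`, `role`,
#'   `path`) with the expressed-gene vector in attribute `"expressed"`.
#' @export
simulate_pileups <- function(truth, parents, cfg, dir, expressed = NULL) {
  stopifnot(inherits(truth, "octo_truth"), inherits(cfg, "sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ref <- parents$parent1$ref
  sim_seed(cfg, "expression")
  if (is.null(expressed))
    expressed <- setNames(runif(nrow(ref$genes)) < cfg$expressed_frac,
                          ref$genes$gene_id)
  # gene expression level relative to the library mean, shared across
  # individuals (lognormal with mean 1)
  expr_level <- setNames(
    stats::rlnorm(nrow(ref$genes), -cfg$expr_sdlog^2 / 2, cfg$expr_sdlog),
    ref$genes$gene_id)
  sim_seed(cfg, "pileup")
  sites <- truth$sites
  keep <- expressed[sites$gene_id]
  s <- sites[keep, , drop = FALSE]
  copies <- truth$copies[keep, , drop = FALSE]
  ord <- order(s$gene_id, s$offset)
  s <- s[ord, , drop = FALSE]
  copies <- copies[ord, , drop = FALSE]

  parent_copies <- function(lab) ifelse(s$parent == lab, s$dose, 0L)
  roles <- c("parent1", "parent2", rep("progeny", length(truth$progeny)))
  ids <- c("P1", "P2", truth$progeny)
  paths <- file.path(dir, paste0(ids, ".pileup"))
  for (i in seq_along(ids)) {
    cp <- switch(roles[i], parent1 = parent_copies("P1"),
                 parent2 = parent_copies("P2"),
                 copies[, ids[i]])
    mu <- if (roles[i] == "progeny") cfg$mean_depth else cfg$parent_depth_mean
    w <- cfg$hap_expr_weights
    pfrac <- if (!is.null(w) && roles[i] != "progeny") {
      # expression-weighted allele fraction for the parent's own sites
      vapply(seq_len(nrow(s)), function(k) {
        if (cp[k] == 0) return(0)
        sum(w[as.integer(strsplit(s$carriers[k], ",")[[1]])])
      }, numeric(1))
    } else cp / cfg$ploidy
    lines <- pileup_lines(s, cp, pfrac, mu * expr_level, cfg)
    writeLines(lines, paths[i])
  }
  sheet <- data.frame(sample_id = ids, role = roles, path = paths,
                      stringsAsFactors = FALSE)
  attr(sheet, "expressed") <- expressed
  invisible(sheet)
}

# Build pileup text lines for one individual.  `pfrac` is the per-site
# minor-allele sampling probability; `mu` a named per-gene expected depth.
pileup_lines <- function(s, cp, pfrac, mu, cfg) {
  genes <- unique(s$gene_id)
  gdepth <- setNames(rnbinom(length(genes), size = cfg$depth_dispersion,
                             mu = mu[genes]), genes)
  d <- as.integer(gdepth[s$gene_id])
  use <- d > 0L
  if (!any(use)) return(character(0))
  s <- s[use, , drop = FALSE]; d <- d[use]
  pfrac <- pfrac[use]
  n <- nrow(s)
  nalt <- rbinom(n, d, pfrac)
  nref <- d - nalt
  # sequencing errors: E reads per line get a uniformly drawn base
  extra <- character(n)
  nerr <- rbinom(n, d, cfg$base_error)
  for (i in which(nerr > 0)) {
    from_alt <- sample.int(d[i], nerr[i]) <= nalt[i]
    nalt[i] <- nalt[i] - sum(from_alt)
    nref[i] <- nref[i] - sum(!from_alt)
    newb <- sample(DNA_BASES4, nerr[i], replace = TRUE)
    extra[i] <- paste(ifelse(newb == s$ref[i], ".",
                             ifelse(newb == s$alt[i], toupper(s$alt[i]), newb)),
                      collapse = "")
  }
  rf <- rbinom(n, nref, 0.5)
  af <- rbinom(n, nalt, 0.5)
  bases <- paste0(strrep(".", rf), strrep(",", nref - rf),
                  strrep(toupper(s$alt), af), strrep(tolower(s$alt), nalt - af),
                  extra)
  qpool <- intToUtf8(cfg$qual_levels + 33L, multiple = TRUE)
  qs <- sample(qpool, sum(d), replace = TRUE, prob = cfg$qual_probs)
  quals <- vapply(split(qs, rep(seq_len(n), d)), paste, character(1),
                  collapse = "")
  paste(s$gene_id, s$offset + 1L, s$ref, d, bases, quals, sep = "\t")
}

#' Run the full synthetic cross end to end
#'
#' Convenience orchestrator: builds the base reference, injects the
#' translocation plan into the two species' genomes, spikes parental
#' variants, simulates meiosis for all progeny and (optionally) writes
#' per-individual pileups plus the anchor table and truth TSVs.
#'
#' @inheritParams build_reference
#' @param plan Optional [rearrangement_plan()].
#' @param dir Optional output directory; when given, pileups and TSVs are
#'   written and a sample sheet returned in `$samples`.
#' @return A list: `ref` (base reference), `ref_a`/`ref_b` (species
#'   references), `parents`, `truth`, `events`, `anchors`, and when `dir`
#'   is given `samples` plus file paths.
#' @export
simulate_cross <- function(cfg, plan = NULL, dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  ref <- build_reference(cfg)
  inj <- inject_rearrangements(ref, ref, plan)
  parents <- spike_variants(ref, cfg)
  parents$parent1$ref <- inj$ref_a
  parents$parent2$ref <- inj$ref_b
  truth <- simulate_progeny(parents$parent1, parents$parent2, cfg)
  out <- list(ref = ref, ref_a = inj$ref_a, ref_b = inj$ref_b,
              parents = parents, truth = truth, events = inj$events,
              anchors = anchor_table(ref))
  if (!is.null(dir)) {
    out$samples <- simulate_pileups(truth, parents, cfg, dir)
    write.tsv <- function(x, f) utils::write.table(
      x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
    write.tsv(out$anchors, "anchors.tsv")
    write.tsv(out$samples, "samples.tsv")
    tdir <- file.path(dir, "truth")
    dir.create(tdir, showWarnings = FALSE)
    utils::write.table(truth$sites, file.path(tdir, "sites.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    pres <- data.frame(site_id = rownames(truth$copies),
                       truth$presence * 1L, check.names = FALSE)
    utils::write.table(pres, file.path(tdir, "presence.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (!is.null(out$events))
      utils::write.table(out$events, file.path(tdir, "events.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
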