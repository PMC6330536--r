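test_that("reference building is deterministic and respects preconditions", {
  cfg <- tiny_cfg(seed = 3)
  r1 <- build_reference(cfg)
  r2 <- build_reference(cfg)
  expect_identical(r1, r2)
  r3 <- build_reference(tiny_cfg(seed = 4))
  expect_false(identical(r1$cds, r3$cds))
  expect_identical(length(unique(r1$genes$chrom)), 10L)
  expect_false(any(duplicated(r1$genes$gene_id)))
  # genes within chromosome bounds, non-overlapping, in-frame CDS, no stops
  for (ch in unique(r1$genes$chrom)) {
    g <- r1$genes[r1$genes$chrom == ch, ]
    g <- g[order(g$start), ]
    expect_true(all(g$end <= r1$chromosomes$length[r1$chromosomes$chrom == ch]))
    if (nrow(g) > 1) expect_true(all(head(g$end, -1) <= tail(g$start, -1)))
  }
  expect_true(all(nchar(r1$cds) %% 3 == 0))
  has_stop <- vapply(r1$cds, function(s) {
    n <- nchar(s) %/% 3
    any(substring(s, 3 * seq_len(n) - 2, 3 * seq_len(n)) %in%
          c("TAA", "TAG", "TGA"))
  }, logical(1))
  expect_false(any(has_stop))
  expect_error(sim_config(seed = 1, n_genes = 0), "positive")
})

test_that("variant spiking follows the dosage mixture and carrier rules", {
  cfg <- sim_config(seed = 5, n_genes = 300, snp_rate = 0.08)
  ref <- build_reference(cfg)
  sv <- spike_variants(ref, cfg)
  s <- sv$sites
  expect_gt(nrow(s), 8000)
  # observed single-dose fraction within 3 binomial SE of 0.70
  p_hat <- mean(s$dose == 1)
  se <- sqrt(0.7 * 0.3 / nrow(s))
  expect_lt(abs(p_hat - 0.7), 3 * se)
  # carrier count equals dose, carriers unique, alt differs from ref
  nc <- lengths(strsplit(s$carriers, ","))
  expect_identical(nc, lengths(lapply(strsplit(s$carriers, ","), unique)))
  expect_identical(as.integer(nc), s$dose)
  expect_false(any(s$alt == s$ref))
  # each site belongs to exactly one parent
  expect_setequal(unique(s$parent), c("P1", "P2"))
  expect_identical(nrow(sv$parent1$variants) + nrow(sv$parent2$variants),
                   nrow(s))
  # degenerate mixture: all sites single dose
  cfg1 <- sim_config(seed = 5, n_genes = 60, dosage_mix = c(1, 0, 0, 0))
  s1 <- spike_variants(build_reference(cfg1), cfg1)$sites
  expect_true(all(s1$dose == 1L))
})

test_that("meiosis reproduces hypergeometric segregation per dose class", {
  cfg <- sim_config(seed = 9, n_genes = 250, snp_rate = 0.06, n_progeny = 59)
  sim <- simulate_cross(cfg)
  s <- sim$truth$sites
  expect_gt(nrow(s), 5000)
  pres <- sim$truth$presence
  # chi-square goodness of fit of presence counts per dose class
  for (d in 1:4) {
    rows <- which(s$dose == d)
    n_pres <- sum(pres[rows, ])
    n_tot <- length(rows) * ncol(pres)
    p_exp <- 1 - gamete_absence_prob(d, 8)
    chisq <- stats::chisq.test(c(n_pres, n_tot - n_pres),
                               p = c(p_exp, 1 - p_exp))
    expect_gt(chisq$p.value, 0.001)
  }
})

test_that("recombination between linked sites follows the map distance", {
  cfg <- sim_config(seed = 21, n_genes = 40, n_progeny = 2000)
  ref <- build_reference(cfg)
  # one dose-1 variant in gene 1 and one ~5 cM / ~20 cM away, same homolog
  g1 <- ref$genes$gene_id[ref$genes$chrom == "chr01"]
  pos_cM <- (ref$genes$start[match(g1, ref$genes$gene_id)]) /
    ref$chromosomes$length[1] * 100
  pick <- function(target) g1[which.min(abs(pos_cM - target))]
  for (target in c(5, 20)) {
    v <- data.frame(
      site_id = c("a", "b"), gene_id = c(pick(0), pick(target)),
      offset = 0L, ref = "A", alt = "G", parent = "P1", dose = 1L,
      carriers = "1", stringsAsFactors = FALSE)
    p1 <- structure(list(ref = ref, variants = v, label = "P1", ploidy = 8L),
                    class = "octo_parent")
    p2 <- structure(list(ref = ref, variants = v[0, ], label = "P2",
                         ploidy = 8L), class = "octo_parent")
    tr <- simulate_progeny(p1, p2, cfg)
    d_cM <- abs(diff(tr$sites$cM))
    r_exp <- (1 - exp(-2 * d_cM / 100)) / 2
    r_obs <- mean(tr$presence[1, ] != tr$presence[2, ])
    se <- sqrt(r_exp * (1 - r_exp) / ncol(tr$presence))
    expect_lt(abs(r_obs - r_exp), 3 * se + 1e-9)
  }
})

test_that("sites at zero genetic distance co-segregate perfectly", {
  cfg <- tiny_cfg(seed = 13, n_progeny = 40)
  ref <- build_reference(cfg)
  g <- ref$genes$gene_id[1]
  v <- data.frame(site_id = c("a", "b"), gene_id = g, offset = c(3L, 3L),
                  ref = "A", alt = c("G", "C"), parent = "P1", dose = 1L,
                  carriers = "2", stringsAsFactors = FALSE)
  p1 <- structure(list(ref = ref, variants = v, label = "P1", ploidy = 8L),
                  class = "octo_parent")
  p2 <- structure(list(ref = ref, variants = v[0, ], label = "P2",
                       ploidy = 8L), class = "octo_parent")
  tr <- simulate_progeny(p1, p2, cfg)
  expect_identical(tr$presence[1, ], tr$presence[2, ])
})

test_that("the full simulator is byte-identical under a fixed seed", {
  cfg <- tiny_cfg(seed = 31)
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  s1 <- simulate_cross(cfg, dir = d1)
  s2 <- simulate_cross(cfg, dir = d2)
  expect_identical(s1$truth$sites, s2$truth$sites)
  expect_identical(s1$truth$copies, s2$truth$copies)
  for (f in basename(s1$samples$path)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("translocation injection moves blocks and keeps anchors intact", {
  cfg <- sim_config(seed = 2, n_genes = 100)
  ref <- build_reference(cfg)
  plan <- rearrangement_plan(
    src_chrom = c("chr01", "chr03", "chr05"),
    from_gene = c(2, 4, 1), n_genes = c(5, 3, 3),
    dst_chrom = c("chr02", "chr04", "chr06"),
    insert_after = c(3, 0, 5),
    scope = c("shared", "shared", "A"))
  inj <- inject_rearrangements(ref, ref, plan)
  expect_identical(sum(inj$events$species == "A"), 3L)
  expect_identical(sum(inj$events$species == "B"), 2L)
  expect_identical(sum(inj$events$shared & inj$events$species == "A"), 2L)
  # moved genes reside on the target chromosome but anchor to the source
  moved <- strsplit(inj$events$gene_ids[1], ",")[[1]]
  expect_identical(length(moved), 5L)
  anc <- anchor_table(ref)
  expect_true(all(anc$chrom[match(moved, anc$gene_id)] == "chr01"))
  expect_true(all(inj$ref_a$genes$chrom[
    match(moved, inj$ref_a$genes$gene_id)] == "chr02"))
  # private event applied to species A only
  movedA <- strsplit(inj$events$gene_ids[3], ",")[[1]]
  expect_true(all(inj$ref_b$genes$chrom[
    match(movedA, inj$ref_b$genes$gene_id)] == "chr05"))
  # empty plan leaves references untouched
  inj0 <- inject_rearrangements(ref, ref, NULL)
  expect_identical(inj0$ref_a, ref)
  expect_identical(nrow(inj0$events), 0L)
  # invalid plans are rejected
  expect_error(rearrangement_plan("chr01", 1, 2, "chr02", 0), "3 genes")
  expect_error(rearrangement_plan(c("chr01", "chr01"), c(1, 3), c(3, 3),
                                  c("chr02", "chr03"), c(0, 0)),
               "overlap")
  expect_error(rearrangement_plan(c("chr01", "chr02"), c(1, 1), c(3, 3),
                                  c("chr02", "chr03"), c(0, 0)),
               "source and target")
})

test_that("simulated pileups carry the expected allele fractions", {
  cfg <- sim_config(seed = 17, n_genes = 120, n_progeny = 59,
                    base_error = 0, expressed_frac = 1)
  sim <- simulate_cross(cfg, dir = file.path(tempdir(), "simC"))
  cols <- lapply(sim$samples$path, read_pileup)
  names(cols) <- sim$samples$sample_id
  s <- sim$truth$sites
  # merged progeny pooled alt fraction at parental dose-1 sites ~ 1/16
  merged <- merge_columns(cols[sim$truth$progeny])
  key <- paste0(merged$seqname, ":", merged$pos)
  d1 <- match(s$site_id[s$dose == 1], key)
  cnt <- as.matrix(merged[, c("A", "C", "G", "T")])
  alt_n <- cnt[cbind(d1, match(s$alt[s$dose == 1], c("A", "C", "G", "T")))]
  tot <- rowSums(cnt)[d1]
  frac <- sum(alt_n) / sum(tot)
  se <- sqrt(1 / 16 * 15 / 16 / sum(tot))
  expect_lt(abs(frac - 1 / 16), 3 * se)
  # error rate 0: non-carrier parent has zero alt reads at the other's sites
  p2 <- cols[["P2"]]
  k2 <- match(s$site_id[s$parent == "P1"], paste0(p2$seqname, ":", p2$pos))
  cnt2 <- as.matrix(p2[, c("A", "C", "G", "T")])
  alt2 <- cnt2[cbind(k2, match(s$alt[s$parent == "P1"], c("A", "C", "G", "T")))]
  expect_true(all(alt2[!is.na(k2)] == 0))
  unlink(file.path(tempdir(), "simC"), recursive = TRUE)
})
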