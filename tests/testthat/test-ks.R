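test_that("CDS validation strips terminal stops and rejects broken frames", {
  seqs <- Biostrings::DNAStringSet(c(
    ok = strrep("GGT", 40),
    stopped = paste0(strrep("GCA", 40), "TAA"),
    internal = paste0(strrep("GGT", 10), "TAG", strrep("GGT", 30)),
    offframe = paste0(strrep("GGT", 40), "GG"),
    short = strrep("GGT", 10)))
  expect_warning(v <- read_cds(seqs), "excluded")
  expect_setequal(names(v), c("ok", "stopped"))
  expect_identical(Biostrings::width(v)[names(v) == "stopped"], 120L)
  # exact duplicates removed
  dup <- Biostrings::DNAStringSet(c(a = strrep("GGT", 40),
                                    b = strrep("GGT", 40)))
  expect_warning(v2 <- read_cds(dup), "duplicate")
  expect_identical(names(v2), "a")
})

test_that("reciprocal best hits require mutual uniqueness", {
  base <- strrep("ATGGCTAAAGGTCCTGTTACTGAATGGCGT", 5)  # 50 codons
  mut <- function(s, at) {
    # non-synonymous first-position changes, keeps frame and no stops
    for (p in at) substr(s, 3 * p + 1, 3 * p + 1) <- "C"
    s
  }
  A <- Biostrings::DNAStringSet(c(A1 = base, A2 = mut(base, 1:10)))
  B <- Biostrings::DNAStringSet(c(B1 = mut(base, 1),
                                  B2 = mut(base, c(1:10, 20:25))))
  rbh <- reciprocal_best_hits(read_cds(A), read_cds(B))
  expect_identical(rbh$id_b[rbh$id_a == "A1"], "B1")
  expect_identical(rbh$id_b[rbh$id_a == "A2"], "B2")
  # a tie for best hit drops the query: two identical subjects
  B2 <- Biostrings::DNAStringSet(c(B1 = mut(base, 1), B1bis = mut(base, 2)))
  aaB <- Biostrings::translate(B2)
  if (as.character(aaB[[1]]) == as.character(aaB[[2]])) {
    rbh2 <- reciprocal_best_hits(read_cds(A)["A1"], read_cds(B2))
    expect_identical(nrow(rbh2), 0L)
  }
})

test_that("codon alignment removes gap columns and honours coverage", {
  s <- strrep("ATGGCTAAAGGTCCTGTTACTGAATGGCGT", 4)  # 40 codons
  aln <- codon_align(s, s)
  expect_identical(aln$length, 40L)
  expect_identical(aln$codons_a, aln$codons_b)
  # deleting one internal codon drops exactly that column
  del <- paste0(substr(s, 1, 30), substr(s, 34, nchar(s)))
  aln2 <- codon_align(s, del)
  expect_identical(aln2$length, 39L)
  expect_identical(paste(aln2$codons_b, collapse = ""), del)
  # coverage boundary is strict ("exceeding" one half)
  half <- structure(list(codons_a = rep("GGT", 20), codons_b = rep("GGT", 20),
                         length = 20L), class = "codon_alignment")
  expect_false(length_filter(half, ref_len_codons = 40))
  expect_true(length_filter(half, ref_len_codons = 39))
  expect_true(length_filter(aln, ref_len_codons = 40))
})

test_that("Nei-Gojobori counts match hand-derived examples", {
  # identical sequences: zero divergence
  aln <- codon_align(strrep("GGT", 6), strrep("GGT", 6))
  est0 <- nei_gojobori_ks(aln)
  expect_identical(est0$ks, 0)
  # six-codon pair with one synonymous third-position change:
  # S = 6, sd = 1, ps = 1/6, Ks = -(3/4) ln(1 - 2/9)
  aln1 <- codon_align(strrep("GGT", 6), paste0(strrep("GGT", 5), "GGC"))
  est1 <- nei_gojobori_ks(aln1)
  expect_equal(est1$S, 6)
  expect_equal(est1$sd, 1)
  expect_equal(est1$ps, 1 / 6)
  expect_equal(est1$ks, 0.188485821211, tolerance = 1e-9)
  # per-codon synonymous sites: TTT has exactly 1/3 (only TTT->TTC)
  expect_equal(oracle_syn_sites("TTT"), 1 / 3)
  aln3 <- list(codons_a = "TTT", codons_b = "TTT")
  expect_equal(nei_gojobori_ks(aln3)$S, 1 / 3)
  # methionine and tryptophan codons carry no synonymous sites
  expect_equal(nei_gojobori_ks(list(codons_a = c("ATG", "GGA"),
                                    codons_b = c("ATG", "GGA")))$S, 1)
  # saturation is an error
  expect_error(nei_gojobori_ks(list(codons_a = c("GGT", "GGC"),
                                    codons_b = c("GGA", "GGG"))), "saturated")
})

test_that("pathway averaging matches the exhaustive oracle on random alignments", {
  set.seed(91)
  for (rep in 1:40) {
    ca <- sample(all_sense_codons, 20, replace = TRUE)
    cb <- sample(all_sense_codons, 20, replace = TRUE)
    aln <- list(codons_a = ca, codons_b = cb)
    want <- oracle_ng86(ca, cb)
    if (want$ps >= 0.75) next
    got <- nei_gojobori_ks(aln)
    expect_equal(got$S, want$S, tolerance = 1e-12)
    expect_equal(got$sd, want$sd, tolerance = 1e-12)
    expect_equal(got$ks, want$ks, tolerance = 1e-12)
  }
})

test_that("Ks is monotone in the synonymous difference proportion", {
  ps <- seq(0.01, 0.7, by = 0.05)
  ks <- -0.75 * log(1 - 4 / 3 * ps)
  expect_true(all(diff(ks) > 0))
  # and the estimator inherits it: more third-position changes, larger Ks
  base <- rep("GGT", 30)
  ks_obs <- vapply(1:6, function(k) {
    other <- base; other[seq_len(k)] <- "GGC"
    nei_gojobori_ks(list(codons_a = base, codons_b = other))$ks
  }, numeric(1))
  expect_true(all(diff(ks_obs) > 0))
})

test_that("divergence dating uses the lower median and the clock rate", {
  d <- divergence_time(0.010)
  expect_equal(d$years, 0.010 / (2 * 6.5e-9))
  expect_identical(d$mya, 0.769)
  expect_identical(divergence_time(0)$years, 0)
  # lower median for even counts
  expect_equal(divergence_time(c(0.02, 0.01))$median_ks, 0.01)
  expect_equal(divergence_time(c(0.03, 0.01, 0.02))$median_ks, 0.02)
  expect_error(divergence_time(numeric(0)), "finite")
  expect_error(divergence_time(NA_real_), "finite")
  # linear in the median (exact)
  expect_identical(divergence_time(0.2)$years, 10 * divergence_time(0.02)$years)
})

test_that("the full Ks pipeline dates a simulated ortholog set", {
  set.seed(99)
  # build a small gene family: B is the reference set, A a diverged copy
  mk <- function(n) paste(sample(setdiff(names(Biostrings::GENETIC_CODE),
                                         c("TAA", "TAG", "TGA")),
                                 n, replace = TRUE), collapse = "")
  genes <- vapply(rep(60, 8), mk, character(1))
  mutate3 <- function(s, p) {
    cod <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    four <- substr(cod, 1, 2) %in% c("GC", "GG", "CC", "AC", "GT")
    hit <- which(four & runif(length(cod)) < p)
    for (i in hit) {
      b <- substr(cod[i], 3, 3)
      substr(cod[i], 3, 3) <- sample(setdiff(c("A", "C", "G", "T"), b), 1)
    }
    paste(cod, collapse = "")
  }
  A <- Biostrings::DNAStringSet(setNames(vapply(genes, mutate3, character(1),
                                                p = 0.2),
                                         sprintf("a%02d", 1:8)))
  B <- Biostrings::DNAStringSet(setNames(genes, sprintf("b%02d", 1:8)))
  out <- ks_pipeline(A, B)
  expect_identical(nrow(out$pairs), 8L)
  expect_true(all(is.finite(out$pairs$ks)))
  expect_gt(out$divergence$median_ks, 0)
  expect_lt(out$divergence$median_ks, 0.5)
  expect_identical(out$divergence$n_pairs, 8L)
})
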