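mk_map <- function(groups) {
  # groups: named list group -> chrom vector (marker anchors, in map order)
  mm <- do.call(rbind, lapply(names(groups), function(g) {
    data.frame(group = g, order = seq_along(groups[[g]]),
               marker_id = paste0(g, "_m", seq_along(groups[[g]])),
               stringsAsFactors = FALSE)
  }))
  anchors <- data.frame(marker_id = mm$marker_id,
                        chrom = unlist(groups, use.names = FALSE),
                        start = seq_len(nrow(mm)) * 1000L,
                        stringsAsFactors = FALSE)
  list(mm = mm, anchors = anchors)
}

test_that("homologous groups follow the anchored-marker majority", {
  x <- mk_map(list(LG1 = c(rep("chr3", 20), rep("chr7", 4)),
                   LG2 = rep("chr1", 12)))
  hg <- assign_hg(x$mm, x$anchors)
  expect_identical(hg$chrom[hg$group == "LG1"], "chr3")
  expect_identical(hg$congruous[hg$group == "LG1"], 20L)
  expect_identical(hg$total[hg$group == "LG1"], 24L)
  expect_equal(hg$congruous_frac[hg$group == "LG1"], 20 / 24)
  expect_equal(hg$congruous_frac[hg$group == "LG2"], 1)
  # "other" anchors count in totals but never win the majority
  y <- mk_map(list(LG1 = c(rep("other", 6), rep("chr2", 4))))
  hgy <- assign_hg(y$mm, y$anchors)
  expect_identical(hgy$chrom, "chr2")
  expect_identical(hgy$total, 10L)
  expect_identical(hgy$congruous, 4L)
})

test_that("majority ties break by longest adjacent run, then chromosome id", {
  # 5 consecutive chr2 markers vs 5 scattered chr9 markers
  z <- mk_map(list(LG1 = c("chr9", rep("chr2", 5), "chr9", "chr9", "chr9",
                           "chr9")))
  hg <- assign_hg(z$mm, z$anchors)
  expect_identical(hg$chrom, "chr2")
  expect_true(hg$tie)
  # fully symmetric tie falls back to the lowest chromosome id
  w <- mk_map(list(LG1 = c(rep("chr5", 3), rep("chr2", 3))))
  expect_identical(assign_hg(w$mm, w$anchors)$chrom, "chr2")
})

test_that("congruous summaries reproduce the worked percentages", {
  expect_equal(round(congruous_percent(2798, 3078), 1), 90.9)
  expect_equal(round(congruous_percent(4018, 4629), 1), 86.8)
  expect_equal(congruous_percent(10, 10), 100)
  x <- mk_map(list(LG1 = c(rep("chr3", 20), rep("chr7", 4)),
                   LG2 = rep("chr1", 12)))
  cs <- congruous_summary(assign_hg(x$mm, x$anchors))
  expect_identical(cs$congruous, 32L)
  expect_identical(cs$total, 36L)
  # overall fraction is the marker-weighted mean of group fractions (exact)
  expect_identical(cs$percent,
                   100 * sum(cs$per_group$congruous) / sum(cs$per_group$total))
})

test_that("foreign blocks of three or more markers become events", {
  x <- mk_map(list(LG1 = c(rep("chr3", 20), rep("chr7", 4)),
                   LG2 = c(rep("chr3", 20), rep("chr7", 2)),
                   LG3 = c(rep("chr3", 20), rep("chr7", 3), rep("chr9", 5)),
                   LG4 = c(rep("chr2", 10), rep("other", 3))))
  hg <- assign_hg(x$mm, x$anchors)
  ev <- detect_events(x$mm, x$anchors, hg)
  expect_identical(nrow(ev[ev$group == "LG1", ]), 1L)
  expect_identical(ev$support[ev$group == "LG1"], 4L)
  expect_identical(nrow(ev[ev$group == "LG2", ]), 0L)   # below threshold
  expect_identical(nrow(ev[ev$group == "LG3", ]), 2L)   # one per chromosome
  expect_identical(nrow(ev[ev$group == "LG4", ]), 0L)   # "other" never counts
})

test_that("shared-event bookkeeping matches the pair-matching rules", {
  evA <- data.frame(group = c("LG1", "LG2", "LG3"),
                    majority = c("chr1", "chr1", "chr4"),
                    foreign = c("chr5", "chr5", "chr9"),
                    support = 3L, marker_ids = "", stringsAsFactors = FALSE)
  evB <- data.frame(group = "LG7", majority = "chr5", foreign = "chr1",
                    support = 4L, marker_ids = "", stringsAsFactors = FALSE)
  sh <- shared_events(evA, evB)
  # the chr1|chr5 pair is shared regardless of orientation; two A groups
  # witness it, both count as shared events
  expect_identical(sh$shared_pairs, "chr1|chr5")
  expect_identical(sh$n_shared, 3L)
  expect_equal(sh$percent_shared, 100 * 3 / 4)
  # symmetry
  sh2 <- shared_events(evB, evA)
  expect_identical(sh2$shared_pairs, sh$shared_pairs)
  expect_identical(sh2$n_shared, sh$n_shared)
  # disjoint maps share nothing; identical single events share everything
  expect_identical(shared_events(evA[3, ], evB)$n_shared, 0L)
  expect_equal(shared_events(evB, evB)$percent_shared, 100)
  # the published counts: 24 shared of 53 + 18 combined events
  expect_equal(round(shared_percent(24, 53 + 18), 1), 33.8)
})

test_that("collinearity is scored by rank correlation of congruous markers", {
  x <- mk_map(list(LG1 = rep("chr1", 10)))
  hg <- assign_hg(x$mm, x$anchors)
  cl <- collinearity_stats(x$mm, x$anchors, hg)
  expect_equal(cl$rho, 1)
  # reversed map order gives rho = -1
  xr <- x
  xr$mm$order <- rev(xr$mm$order)
  expect_equal(collinearity_stats(xr$mm, xr$anchors, hg)$rho, -1)
  # an internal inversion breaks perfect collinearity
  xi <- x
  xi$mm$order[3:7] <- rev(xi$mm$order[3:7])
  rho <- collinearity_stats(xi$mm, xi$anchors, hg)$rho
  expect_lt(abs(rho), 1)
  # too few congruous markers: not scored
  small <- mk_map(list(LG1 = rep("chr1", 4)))
  expect_true(is.na(collinearity_stats(small$mm, small$anchors,
                                       assign_hg(small$mm, small$anchors))$rho))
})
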