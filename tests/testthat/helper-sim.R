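# Small shared fixtures, built in code.

tiny_cfg <- function(seed = 7, n_progeny = 12, ...) {
  sim_config(seed = seed, n_genes = 40, n_progeny = n_progeny, ...)
}

# write a pileup file from raw lines; returns the path
write_pileup_lines <- function(lines) {
  f <- tempfile(fileext = ".pileup")
  writeLines(lines, f)
  f
}

q40 <- function(n) strrep(rawToChar(as.raw(33 + 40)), n)

# generate 1:1 presence vectors for markers on one homolog at given cM
# positions, recombining under Haldane (crossovers as a Poisson process) --
# an independent generative model for linkage tests
haldane_markers <- function(pos_cM, n_ind) {
  g <- matrix(NA_integer_, length(pos_cM), n_ind)
  for (j in seq_len(n_ind)) {
    state <- sample(0:1, 1)
    v <- integer(length(pos_cM))
    v[1] <- state
    for (i in seq_along(pos_cM)[-1]) {
      d <- pos_cM[i] - pos_cM[i - 1]
      r <- (1 - exp(-2 * d / 100)) / 2
      if (runif(1) < r) state <- 1L - state
      v[i] <- state
    }
    g[, j] <- v
  }
  rownames(g) <- sprintf("m%03d", seq_along(pos_cM))
  colnames(g) <- sprintf("I%03d", seq_len(n_ind))
  g
}
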