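# Independent oracles used across the suite.  These deliberately re-derive
# results by brute force / enumeration, not by calling the implementation.

# Monte-Carlo gamete segregation: sample ploidy/2 homologs without
# replacement and count gametes carrying none of homologs 1..dose.
mc_gamete_absence <- function(dose, ploidy, n_draws = 1e5) {
  m <- ploidy / 2
  hits <- replicate(n_draws, !any(sample.int(ploidy, m) <= dose))
  p <- mean(hits)
  list(p = p, se = sqrt(max(p * (1 - p), 1 / n_draws) / n_draws))
}

# Exact hypergeometric enumeration over all C(ploidy, m) gametes.
enum_gamete_absence <- function(dose, ploidy) {
  m <- ploidy / 2
  g <- utils::combn(ploidy, m)
  mean(apply(g, 2, function(x) !any(x <= dose)))
}

# --- independent Nei-Gojobori pathway oracle -------------------------------

.oracle_code <- Biostrings::GENETIC_CODE
.oracle_stops <- names(.oracle_code)[.oracle_code == "*"]

# synonymous sites of one codon by enumerating its 9 single-base changes
oracle_syn_sites <- function(codon) {
  bases <- c("A", "C", "G", "T")
  s <- 0
  cs <- strsplit(codon, "")[[1]]
  for (pos in 1:3) for (b in bases[bases != cs[pos]]) {
    alt <- cs; alt[pos] <- b; alt <- paste(alt, collapse = "")
    if (!(alt %in% .oracle_stops) &&
        .oracle_code[[alt]] == .oracle_code[[codon]]) s <- s + 1 / 3
  }
  s
}

# enumerate every full mutational pathway between two codons (recursive
# ordering generation), drop those crossing a stop codon, average counts;
# if all are blocked, average over every pathway.
oracle_pair_diffs <- function(c1, c2) {
  paths <- list()
  walk <- function(cur, remaining, syn, nons, blocked) {
    if (length(remaining) == 0) {
      paths[[length(paths) + 1]] <<- c(syn = syn, nd = nons,
                                       blocked = as.numeric(blocked))
      return(invisible())
    }
    for (pos in remaining) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(c2, pos, pos)
      hit_stop <- nxt %in% .oracle_stops
      s_step <- !hit_stop && .oracle_code[[nxt]] == .oracle_code[[cur]]
      walk(nxt, setdiff(remaining, pos),
           syn + as.numeric(s_step), nons + as.numeric(!hit_stop && !s_step),
           blocked || hit_stop)
    }
  }
  d <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (length(d) == 0) return(c(sd = 0, nd = 0))
  walk(c1, d, 0, 0, FALSE)
  m <- do.call(rbind, paths)
  ok <- m[, "blocked"] == 0
  if (!any(ok)) return(oracle_pair_diffs_unblocked(c1, c2))
  m <- m[ok, , drop = FALSE]
  c(sd = mean(m[, "syn"]), nd = mean(m[, "nd"]))
}

oracle_pair_diffs_unblocked <- function(c1, c2) {
  paths <- list()
  walk <- function(cur, remaining, syn, nons) {
    if (length(remaining) == 0) {
      paths[[length(paths) + 1]] <<- c(syn = syn, nd = nons)
      return(invisible())
    }
    for (pos in remaining) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(c2, pos, pos)
      s_step <- !(nxt %in% .oracle_stops) &&
        .oracle_code[[nxt]] == .oracle_code[[cur]]
      walk(nxt, setdiff(remaining, pos),
           syn + as.numeric(s_step), nons + as.numeric(!s_step))
    }
  }
  d <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  walk(c1, d, 0, 0)
  m <- do.call(rbind, paths)
  c(sd = mean(m[, "syn"]), nd = mean(m[, "nd"]))
}

# full oracle Ks for two codon vectors
oracle_ng86 <- function(codons_a, codons_b) {
  S <- (sum(vapply(codons_a, oracle_syn_sites, numeric(1))) +
          sum(vapply(codons_b, oracle_syn_sites, numeric(1)))) / 2
  sd_tot <- sum(vapply(seq_along(codons_a), function(i)
    oracle_pair_diffs(codons_a[i], codons_b[i])[["sd"]], numeric(1)))
  ps <- sd_tot / S
  list(S = S, sd = sd_tot, ps = ps,
       ks = if (ps < 0.75) -0.75 * log(1 - 4 / 3 * ps) else NA_real_)
}

all_sense_codons <- setdiff(names(.oracle_code), .oracle_stops)
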