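# Independent oracles used across test files. These deliberately avoid the
# package's own code paths.

# Brute-force per-column scan of an alignment matrix (rows x columns of
# single characters): returns positions (1-based columns) with >= 2
# distinct A/C/G/T bases, with allele tables and support.
oracle_column_scan <- function(rows) {
  mat <- do.call(rbind, strsplit(rows, ""))
  out <- list()
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    obs <- col[col %in% c("A", "C", "G", "T")]
    tab <- sort(table(obs), decreasing = TRUE)
    if (length(tab) >= 2) {
      out[[length(out) + 1L]] <- list(column = j, alleles = tab,
                                      support = length(obs))
    }
  }
  out
}

# Reverse complement by explicit lookup, independent of Biostrings.
oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(unname(comp[strsplit(s, "")[[1]]])), collapse = "")
}

# One-way ANOVA by explicit sums of squares.
oracle_oneway_F <- function(values, groups) {
  groups <- as.character(groups)
  gm <- mean(values)
  ssb <- 0; ssw <- 0
  for (g in unique(groups)) {
    v <- values[groups == g]
    ssb <- ssb + length(v) * (mean(v) - gm)^2
    ssw <- ssw + sum((v - mean(v))^2)
  }
  df1 <- length(unique(groups)) - 1
  df2 <- length(values) - length(unique(groups))
  list(F = (ssb / df1) / (ssw / df2), df1 = df1, df2 = df2)
}

# Benjamini-Hochberg step-up by hand.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# Cohen's kappa from a 2x2 table of counts.
oracle_kappa <- function(a, b, c, d) {
  n <- a + b + c + d
  po <- (a + d) / n
  pe <- ((a + b) * (a + c) + (c + d) * (b + d)) / n^2
  (po - pe) / (1 - pe)
}

# Small default probe bank + experiment used by several files.
make_small_experiment <- function(n_ps = 10, ai_delta = 0, sex_effect = 0,
                                  noise_sd = 0.2, seed = 11) {
  bank <- random_probe_bank(n_ps, seed = seed)
  ex <- simulate_experiment(
    bank,
    params = sim_params(ai_delta = ai_delta, sex_effect = sex_effect,
                        noise_sd = noise_sd),
    seed = seed + 1)
  ex
}
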