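# Shared fixture builders: everything is generated in code at test time.

# Outcome matrix from a plain matrix of 0/1/NA, labelled A, B, C, ...
om <- function(values, strata = NULL, strata_name = if (!is.null(strata)) "s") {
  values <- as.matrix(values)
  colnames(values) <- LETTERS[seq_len(ncol(values))]
  outcome_matrix(values, strata = strata, strata_name = strata_name)
}

# Write a small CSV to a temp file and return its path.
write_csv_fixture <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}

# Hand-built results row, for exercising classification/graph logic
# independently of the bootstrap.
mk_result <- function(source, target, iota, ci_low, ci_high,
                      stratum = "", n = 100) {
  data.frame(source = source, target = target, stratum = stratum, n = n,
             a = 1, b = 1, c = 1, d = 1, iota = iota,
             ci_low = ci_low, ci_high = ci_high,
             significant = ci_low > 0 || ci_high < 0,
             gras_intensity = NA_real_, degenerate_fraction = 0,
             n_replicates = 1000, seed = 1, stringsAsFactors = FALSE)
}

# Independent oracle: the implication index evaluated as one closed-form
# expression on raw counts (single log of a product ratio), kept separate
# from the package's smoothed-probability code path.
oracle_iota <- function(a, b, c, d, alpha = 0.5) {
  0.5 * log(((a + alpha) * (d + alpha) * (a + b + 2 * alpha) * (b + d + 2 * alpha)) /
            ((b + alpha)^2 * (a + c + 2 * alpha) * (c + d + 2 * alpha)))
}

# Independent oracle: Poisson upper-tail P(N >= b) by brute-force
# summation of the lower tail in log space.
oracle_poisson_tail <- function(b, lambda) {
  if (b <= 0) return(1)
  k <- 0:(b - 1)
  1 - sum(exp(k * log(lambda) - lambda - lgamma(k + 1)))
}

# Random fourfold tables under a fixed seed.
random_tables <- function(n_tables, max_count = 30, seed = 42) {
  set.seed(seed)
  t(replicate(n_tables, {
    repeat {
      x <- sample(0:max_count, 4, replace = TRUE)
      if (sum(x) >= 1) return(x)
    }
  }))
}
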