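#' Bootstrap configuration
#'
#' Settings for pairwise bootstrap inference. Subjects (rows) are the
#' resampling unit; each replicate redraws n subjects with replacement and
#' recomputes the implication index on the replicate's fourfold table.
#' Significance of a directed pair is declared when the confidence
#' interval of the replicate distribution excludes zero.
#'
#' @param n_replicates number of bootstrap replicates (>= 1).
#' @param level confidence level in (0, 1); 0.95 tests at the 0.05 level.
#' @param seed integer root seed. Every pair (and stratum) derives its own
#'   substream from this root by hashing its labels, so results do not
#'   depend on the order in which pairs are analyzed and adding an outcome
#'   leaves existing pairs untouched.
#' @param alpha smoothing pseudo-count forwarded to [iota_counts()].
#' @param ci_method `"percentile"` (empirical quantiles of the replicate
#'   distribution, the default) or `"normal"` (estimate +/- z * bootstrap
#'   standard error). See the methods vignette for the trade-off.
#' @param adjust `"none"` (default, each pair tested at `1 - level`) or
#'   `"bonferroni"` (per-pair CI level widened to `1 - (1-level)/k` over
#'   the k ordered pairs of a call to [analyze_all_pairs()]).
#' @return An object of class `bootstrap_config`.
#' @export
bootstrap_config <- function(n_replicates = 2000, level = 0.95, seed = 1L,
                             alpha = 0.5,
                             ci_method = c("percentile", "normal"),
                             adjust = c("none", "bonferroni")) {
  stopifnot(n_replicates >= 1, level > 0, level < 1)
  structure(list(n_replicates = as.integer(n_replicates), level = level,
                 seed = as.integer(seed), alpha = alpha,
                 ci_method = match.arg(ci_method),
                 adjust = match.arg(adjust)),
            class = "bootstrap_config")
}

# Deterministic 31-bit substream seed from (root seed, labels).
# Polynomial string hash; exact in double arithmetic (31*h < 2^53).
pair_seed <- function(seed, ...) {
  s <- paste(c(...), collapse = "\r")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  as.integer((h + (as.numeric(seed) %% 2147483647) * 7919) %% 2147483646) + 1L
}

boot_ci <- function(est, replicates, level, ci_method) {
  if (ci_method == "percentile") {
    lo <- (1 - level) / 2
    unname(stats::quantile(replicates, c(lo, 1 - lo), names = FALSE))
  } else {
    z <- stats::qnorm(1 - (1 - level) / 2)
    s <- stats::sd(replicates)
    c(est - z * s, est + z * s)
  }
}

#' Bootstrap inference for one directed pair
#'
#' Estimates the implication index of the ordered pair (A, B), its
#' bootstrap confidence interval, and significance (CI excludes zero).
#' Rows with a missing value in A or B are excluded first. Case
#' resampling is performed exactly: redrawing n rows with replacement
#' induces a multinomial distribution on the fourfold counts, which is
#' sampled directly — replicates are therefore identically distributed to
#' explicit row resampling at a fraction of the cost. Replicates in which
#' a resampled column is constant are kept (smoothing keeps the index
#' finite; rejecting them would bias the interval) and their fraction is
#' reported.
#'
#' @param m an [outcome_matrix()].
#' @param A,B outcome labels: source and target of the directed pair.
#' @param cfg a [bootstrap_config()].
#' @param stratum internal: stratum label carried into the result and the
#'   substream hash.
#' @param level_override internal: per-pair CI level used by the
#'   Bonferroni adjustment.
#' @return An object of class `implication_result`; coerce with
#'   [as.data.frame()] to get the standard results row.
#' @export
bootstrap_pair <- function(m, A, B, cfg = bootstrap_config(),
                           stratum = "", level_override = NULL) {
  stopifnot(inherits(m, "outcome_matrix"), inherits(cfg, "bootstrap_config"))
  t <- crosstab(m, A, B)
  if (t$n < 2) stop("need at least 2 complete cases for pair ", A, " -> ", B)
  level <- if (is.null(level_override)) cfg$level else level_override
  cnt <- c(t$a, t$b, t$c, t$d)
  est <- iota_counts(t$a, t$b, t$c, t$d, alpha = cfg$alpha)

  set.seed(pair_seed(cfg$seed, A, B, stratum))
  M <- stats::rmultinom(cfg$n_replicates, t$n, cnt / t$n)
  repl <- iota_counts(M[1, ], M[2, ], M[3, ], M[4, ], alpha = cfg$alpha)
  ci <- boot_ci(est, repl, level, cfg$ci_method)
  gras <- tryCatch(gras_intensity(t), error = function(e) NA_real_)

  structure(list(
    source = A, target = B, stratum = stratum, n = t$n,
    a = t$a, b = t$b, c = t$c, d = t$d,
    iota = est, ci_low = ci[1], ci_high = ci[2],
    significant = ci[1] > 0 || ci[2] < 0,
    gras_intensity = gras,
    degenerate_margin = degenerate_margin(t$a, t$b, t$c, t$d),
    degenerate_fraction = mean(degenerate_margin(M[1, ], M[2, ], M[3, ], M[4, ])),
    n_replicates = cfg$n_replicates, seed = cfg$seed,
    level = level, alpha = cfg$alpha, ci_method = cfg$ci_method),
    class = "implication_result")
}

#' @export
print.implication_result <- function(x, ...) {
  cat(sprintf("%s => %s%s: iota = %.3f, %.0f%% CI [%.3f, %.3f]%s\n",
              x$source, x$target,
              if (nzchar(x$stratum)) paste0(" [stratum ", x$stratum, "]") else "",
              x$iota, 100 * x$level, x$ci_low, x$ci_high,
              if (x$significant) " *" else ""))
  cat(sprintf("  n = %d, counts (a,b,c,d) = (%d,%d,%d,%d), intensity = %s\n",
              x$n, x$a, x$b, x$c, x$d,
              ifelse(is.na(x$gras_intensity), "NA",
                     sprintf("%.3f", x$gras_intensity))))
  if (x$degenerate_margin) cat("  warning: degenerate margin\n")
  invisible(x)
}

result_columns <- c("source", "target", "stratum", "n", "a", "b", "c", "d",
                    "iota", "ci_low", "ci_high", "significant",
                    "gras_intensity", "degenerate_fraction",
                    "n_replicates", "seed")

#' @export
as.data.frame.implication_result <- function(x, ...) {
  df <- as.data.frame(unclass(x)[result_columns], stringsAsFactors = FALSE)
  class(df) <- c("sia_results", "data.frame")
  df
}

#' Directed implication analysis of every ordered pair
#'
#' Runs [bootstrap_pair()] for every ordered pair of outcomes (k outcomes
#' give k(k-1) directed results). Each pair uses a substream derived from
#' `(seed, source, target)`, so the result of a pair does not depend on
#' which other outcomes are present.
#'
#' @param m an [outcome_matrix()] with at least 2 outcomes; apply
#'   [complete_case_filter()] first to reproduce a complete-case analysis.
#' @param cfg a [bootstrap_config()].
#' @param pairs optional 2-column character matrix (source, target) to
#'   analyze a subset of ordered pairs.
#' @param stratum internal: stratum label for stratified runs.
#' @return A `sia_results` data frame, one row per ordered pair, with
#'   columns `source, target, stratum, n, a, b, c, d, iota, ci_low,
#'   ci_high, significant, gras_intensity, degenerate_fraction,
#'   n_replicates, seed`.
#' @export
analyze_all_pairs <- function(m, cfg = bootstrap_config(), pairs = NULL,
                              stratum = "") {
  stopifnot(inherits(m, "outcome_matrix"))
  if (is.null(pairs)) {
    if (length(m$outcome_names) < 2)
      stop("need at least 2 outcomes for pairwise analysis")
    pairs <- expand.grid(target = m$outcome_names, source = m$outcome_names,
                         stringsAsFactors = FALSE)[, c("source", "target")]
    pairs <- as.matrix(pairs[pairs$source != pairs$target, ])
  }
  level_override <- if (cfg$adjust == "bonferroni")
    1 - (1 - cfg$level) / nrow(pairs) else NULL
  rows <- lapply(seq_len(nrow(pairs)), function(i)
    as.data.frame(bootstrap_pair(m, pairs[i, 1], pairs[i, 2], cfg,
                                 stratum = stratum,
                                 level_override = level_override)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "level") <- cfg$level
  attr(out, "alpha") <- cfg$alpha
  attr(out, "ci_method") <- cfg$ci_method
  attr(out, "adjust") <- cfg$adjust
  class(out) <- c("sia_results", "data.frame")
  out
}

#' Stratified re-analysis
#'
#' Repeats the all-ordered-pairs analysis separately within each level of
#' the binary stratification variable (the post-hoc subgroup design:
#' does an implication hold in both baseline subgroups?). Rows with a
#' missing stratum are excluded; a stratum with fewer than 2 complete
#' rows is skipped with a warning rather than an error. Each stratum uses
#' its own substreams, hashed from `(seed, source, target, stratum)`.
#'
#' @param m an [outcome_matrix()] carrying a strata column (see
#'   [read_outcomes()]'s `strata_column`).
#' @param cfg a [bootstrap_config()].
#' @param pairs optional ordered-pair subset, as in [analyze_all_pairs()].
#' @return A `sia_results` data frame with the `stratum` column set to
#'   `"0"` / `"1"`.
#' @export
stratified_analysis <- function(m, cfg = bootstrap_config(), pairs = NULL) {
  stopifnot(inherits(m, "outcome_matrix"))
  if (is.null(m$strata)) stop("no stratification variable in this matrix")
  out <- list()
  for (s in c(0L, 1L)) {
    keep <- !is.na(m$strata) & m$strata == s
    if (sum(keep) < 2) {
      warning(sprintf("stratum %s = %d skipped: fewer than 2 subjects",
                      m$strata_name, s))
      next
    }
    ms <- subset_rows(m, keep)
    out[[length(out) + 1]] <-
      analyze_all_pairs(ms, cfg, pairs = pairs, stratum = as.character(s))
  }
  if (!length(out)) stop("no stratum with at least 2 subjects")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "level") <- cfg$level
  attr(res, "alpha") <- cfg$alpha
  attr(res, "ci_method") <- cfg$ci_method
  class(res) <- c("sia_results", "data.frame")
  res
}

#' Write a results table to CSV with run provenance
#'
#' The file starts with `#`-prefixed header lines recording seed,
#' replicate count, smoothing, confidence level and package version, so a
#' results file is self-describing and two runs with identical inputs are
#' byte-identical.
#'
#' @param results a `sia_results` data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_results_csv <- function(results, path) {
  stopifnot(inherits(results, "data.frame"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  hdr <- c(
    sprintf("# implicate version: %s",
            as.character(utils::packageVersion("implicate"))),
    sprintf("# seed: %s", results$seed[1]),
    sprintf("# n_replicates: %s", results$n_replicates[1]),
    sprintf("# smoothing_alpha: %s", format(attr(results, "alpha"))),
    sprintf("# level: %s", format(attr(results, "level"))),
    sprintf("# ci_method: %s", attr(results, "ci_method")))
  writeLines(hdr, con)
  utils::write.table(as.data.frame(results)[, result_columns], con,
                     sep = ",", row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Read back a results CSV written by [write_results_csv()]
#' @param path file path.
#' @return A `sia_results` data frame (provenance headers are skipped).
#' @export
read_results_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                        colClasses = c(stratum = "character"))
  class(df) <- c("sia_results", "data.frame")
  df
}
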