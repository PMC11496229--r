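# Independent bootstrap oracle: explicit row resampling, no shared code
# with the package's multinomial implementation.
row_resample_boot <- function(m, A, B, R, seed, alpha = 0.5, level = 0.95) {
  x <- m$values[, A]; y <- m$values[, B]
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]; n <- length(x)
  set.seed(seed)
  repl <- replicate(R, {
    idx <- sample.int(n, n, replace = TRUE)
    xi <- x[idx]; yi <- y[idx]
    iota_counts(sum(xi & yi), sum(xi & !yi), sum(!xi & yi), sum(!xi & !yi),
                alpha = alpha)
  })
  lo <- (1 - level) / 2
  unname(quantile(repl, c(lo, 1 - lo)))
}

test_that("bootstrap results are deterministic given data, config and seed", {
  m <- generate_cohort(hub_cohort_spec(n = 80, seed = 3))
  cfg <- bootstrap_config(n_replicates = 500, seed = 42)
  r1 <- bootstrap_pair(m, "working", "functional", cfg)
  r2 <- bootstrap_pair(m, "working", "functional", cfg)
  expect_identical(r1, r2)

  res1 <- analyze_all_pairs(m, cfg)
  res2 <- analyze_all_pairs(m, cfg)
  expect_identical(res1, res2)

  # different seed, different intervals
  r3 <- bootstrap_pair(m, "working", "functional",
                       bootstrap_config(n_replicates = 500, seed = 43))
  expect_false(identical(r1$ci_low, r3$ci_low))
})

test_that("per-pair substreams do not depend on which other outcomes exist", {
  spec <- hub_cohort_spec(n = 100, seed = 9)
  m4 <- generate_cohort(spec)
  m2 <- outcome_matrix(m4$values[, c("working", "living")],
                       subject_ids = m4$subject_ids)
  cfg <- bootstrap_config(n_replicates = 400, seed = 5)
  full <- analyze_all_pairs(m4, cfg)
  pairo <- analyze_all_pairs(m2, cfg)
  for (col in c("iota", "ci_low", "ci_high", "significant"))
    expect_identical(
      full[full$source == "working" & full$target == "living", col],
      pairo[pairo$source == "working" & pairo$target == "living", col])
})

test_that("a planted perfect implication is detected as significant", {
  spec <- cohort_spec(200, c(A = 0.5, B = NA),
                      links = data.frame(source = "A", target = "B",
                                         eps = 0, q = 0.5), seed = 11)
  m <- generate_cohort(spec)
  r <- bootstrap_pair(m, "A", "B", bootstrap_config(n_replicates = 2000,
                                                    seed = 1))
  expect_true(r$significant)
  expect_gt(r$ci_low, 0)
  expect_equal(r$b, 0L)
  # cross-check the interval against an independent row-resampling
  # implementation at high replicate count
  ci <- row_resample_boot(m, "A", "B", R = 4000, seed = 2)
  r2 <- bootstrap_pair(m, "A", "B", bootstrap_config(n_replicates = 4000,
                                                     seed = 2))
  expect_equal(r2$ci_low, ci[1], tolerance = 0.12)
  expect_equal(r2$ci_high, ci[2], tolerance = 0.12)
  expect_true(ci[1] > 0)
})

test_that("results carry the pinned column set in order", {
  m <- generate_cohort(hub_cohort_spec(n = 60, seed = 2))
  res <- analyze_all_pairs(m, bootstrap_config(n_replicates = 100, seed = 1))
  expect_equal(names(res),
               c("source", "target", "stratum", "n", "a", "b", "c", "d",
                 "iota", "ci_low", "ci_high", "significant",
                 "gras_intensity", "degenerate_fraction",
                 "n_replicates", "seed"))
  expect_equal(nrow(res), 12L)                 # 4 outcomes -> 12 ordered pairs
  expect_true(all(res$ci_low <= res$ci_high))
  expect_equal(res$significant, res$ci_low > 0 | res$ci_high < 0)
  # both directions of a pair are present and generally unequal
  fwd <- res[res$source == "working" & res$target == "living", "iota"]
  bwd <- res[res$source == "living" & res$target == "working", "iota"]
  expect_false(isTRUE(all.equal(fwd, bwd)))
})

test_that("tiny samples and degenerate columns are handled", {
  m1 <- om(matrix(c(1L, 0L), 1, 2))
  expect_error(bootstrap_pair(m1, "A", "B", bootstrap_config(10, seed = 1)),
               "at least 2")
  # constant target column: finite index, degenerate flag, NA intensity
  mc <- om(cbind(c(1, 0, 1, 0), c(1, 1, 1, 1)))
  r <- bootstrap_pair(mc, "A", "B", bootstrap_config(200, seed = 1))
  expect_true(is.finite(r$iota))
  expect_true(r$degenerate_margin)
  expect_true(is.na(r$gras_intensity))
  expect_equal(r$degenerate_fraction, 1)       # every resample constant too
})

test_that("Bonferroni adjustment widens per-pair intervals", {
  m <- generate_cohort(hub_cohort_spec(n = 150, seed = 4))
  plain <- analyze_all_pairs(m, bootstrap_config(1000, seed = 6))
  bonf <- analyze_all_pairs(m, bootstrap_config(1000, seed = 6,
                                                adjust = "bonferroni"))
  expect_true(all(bonf$ci_low <= plain$ci_low + 1e-12))
  expect_true(all(bonf$ci_high >= plain$ci_high - 1e-12))
  expect_lte(sum(bonf$significant), sum(plain$significant))
})

test_that("stratified analysis restricts to each stratum and conserves n", {
  spec <- hub_cohort_spec(n = 300, seed = 12, stratified = TRUE)
  m <- suppressMessages(complete_case_filter(generate_cohort(spec)))
  cfg <- bootstrap_config(500, seed = 3)
  res <- stratified_analysis(m, cfg)
  expect_setequal(unique(res$stratum), c("0", "1"))
  n0 <- res$n[res$stratum == "0"][1]
  n1 <- res$n[res$stratum == "1"][1]
  expect_equal(n0 + n1, nrow(m$values))
  expect_equal(sum(res$stratum == "0"), 12L)

  # constant stratum: one side skipped with a warning, not an error
  mc <- om(matrix(rbinom(80, 1, 0.5), ncol = 2), strata = rep(1L, 40))
  expect_warning(res1 <- stratified_analysis(mc, cfg), "skipped")
  expect_equal(unique(res1$stratum), "1")

  expect_error(stratified_analysis(om(matrix(0:1, 2, 2)), cfg),
               "no stratification")
})

test_that("structure planted in one stratum only is recovered there", {
  spec <- cohort_spec(
    600, c(A = 0.5, B = 0.5),
    links = data.frame(source = "A", target = "B", eps = 0.02, q = 0.2),
    strata = list(name = "s", prevalence = 0.5,
                  overrides = list("1" = list(links = NULL))),
    seed = 21)
  m <- generate_cohort(spec)
  res <- stratified_analysis(m, bootstrap_config(1000, seed = 2),
                             pairs = matrix(c("A", "B"), 1))
  i0 <- res[res$stratum == "0", ]
  i1 <- res[res$stratum == "1", ]
  expect_true(i0$significant)
  expect_gt(i0$iota, i1$iota + 0.5)
  expect_lt(abs(i1$iota), 0.5)                 # independence in stratum 1
})

test_that("interval width shrinks with sample size", {
  widths <- sapply(c(200, 800), function(n) {
    spec <- cohort_spec(n, c(A = 0.5, B = NA),
                        links = data.frame(source = "A", target = "B",
                                           eps = 0.2, q = 0.4), seed = 1)
    med <- sapply(1:8, function(r) {
      m <- generate_cohort(spec, seed = 100 + r)
      res <- bootstrap_pair(m, "A", "B", bootstrap_config(500, seed = r))
      res$ci_high - res$ci_low
    })
    median(med)
  })
  expect_lt(widths[2], widths[1])
})

test_that("results CSV is byte-stable, self-describing and readable", {
  m <- generate_cohort(hub_cohort_spec(n = 70, seed = 15))
  res <- analyze_all_pairs(m, bootstrap_config(300, seed = 9))
  p1 <- tempfile(fileext = ".csv"); p2 <- tempfile(fileext = ".csv")
  write_results_csv(res, p1)
  write_results_csv(analyze_all_pairs(m, bootstrap_config(300, seed = 9)), p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  hdr <- readLines(p1, n = 6)
  expect_true(any(grepl("^# seed: 9$", hdr)))
  expect_true(any(grepl("^# n_replicates: 300$", hdr)))
  back <- read_results_csv(p1)
  expect_equal(back$iota, res$iota, tolerance = 1e-12)
  expect_equal(back$significant, res$significant)
})
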