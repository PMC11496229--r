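#' Full-information implication index (iota-style)
#'
#' An asymmetric index of the directed statistical implication "A implies
#' B" for dichotomous variables, computed on the Jeffreys-smoothed
#' fourfold table. It averages two log-odds comparisons, each penalized by
#' the counterexample cell `p10` (A present, B absent):
#'
#' \deqn{\iota_{A \Rightarrow B} = \tfrac{1}{2}\left[
#'   \ln\frac{\pi_{11}\,\pi_{+0}}{\pi_{10}\,\pi_{+1}} +
#'   \ln\frac{\pi_{00}\,\pi_{1+}}{\pi_{10}\,\pi_{0+}} \right]}
#'
#' The first term is the direct evidence: the odds of B among subjects
#' with A, against the marginal odds of B. The second term is the
#' contrapositive evidence: the odds of not-A among subjects without B,
#' against the marginal odds of not-A — the index exploits that "A implies
#' B" is logically equivalent to "not B implies not A", and is exactly
#' invariant under that relabelling (`iota(a,b,c,d) == iota(d,b,c,a)`).
#'
#' The index ranges over the whole real line: positive values are evidence
#' in favor of the implication, 0 is the independence point, negative
#' values are evidence against. Smoothing guarantees a finite value for
#' every table, including tables with zero counterexamples or a constant
#' column. Magnitudes have no consensual small/medium/large anchors;
#' values are meant to be compared between directions and tested against
#' zero by bootstrap (see [bootstrap_pair()]).
#'
#' Note one structural property (a consequence of the definition, derived
#' in the methods vignette): both bracket terms are positive exactly when
#' the smoothed determinant `p11*p00 - p10*p01` is positive, so the two
#' directed indices of a pair always share their sign; direction is
#' expressed in magnitude, not sign.
#'
#' @param t a [fourfold()] table.
#' @param alpha smoothing pseudo-count passed to [smooth_table()].
#' @return A single finite numeric value.
#' @seealso [iota_counts()] for a vectorized version on raw counts,
#'   [gras_intensity()] for the counterexample-rarity-only comparator.
#' @export
iota <- function(t, alpha = 0.5) {
  stopifnot(inherits(t, "fourfold"))
  iota_counts(t$a, t$b, t$c, t$d, alpha = alpha)
}

#' Implication index from raw cell counts (vectorized)
#'
#' Same statistic as [iota()], taking the four cell counts directly.
#' All four arguments recycle, which is what the bootstrap machinery
#' uses to score thousands of resampled tables at once.
#'
#' @param a,b,c,d cell counts (vectors of equal length or length 1).
#' @param alpha smoothing pseudo-count (> 0).
#' @return Numeric vector of index values.
#' @export
iota_counts <- function(a, b, c, d, alpha = 0.5) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) || alpha <= 0)
    stop("`alpha` must be a positive pseudo-count")
  n <- a + b + c + d
  den <- n + 4 * alpha
  p11 <- (a + alpha) / den; p10 <- (b + alpha) / den
  p01 <- (c + alpha) / den; p00 <- (d + alpha) / den
  0.5 * (log(p11 * (p10 + p00) / (p10 * (p11 + p01))) +
         log(p00 * (p11 + p10) / (p10 * (p01 + p00))))
}

#' Counterexample-rarity implication intensity
#'
#' The classical implication intensity: under independence the number of
#' counterexamples of "A implies B" (cell `b`) is approximately Poisson
#' with mean `lambda = (a+b)(b+d)/n`; the intensity is the upper tail
#' probability `P(N >= b)`, close to 1 when counterexamples are rarer
#' than chance predicts. Unlike [iota()] it uses no contrapositive
#' information — it is the "rarity of counterexamples only" comparator.
#'
#' Undefined when a margin is empty (`a + b = 0` or `b + d = 0`): a
#' constant variable carries no implicative information.
#'
#' @param t a [fourfold()] table.
#' @return Intensity in `[0, 1]`.
#' @export
gras_intensity <- function(t) {
  stopifnot(inherits(t, "fourfold"))
  nA <- t$a + t$b
  nnotB <- t$b + t$d
  if (nA < 1 || nnotB < 1) stop("implication undefined for empty margin")
  lambda <- nA * nnotB / t$n
  stats::ppois(t$b - 1, lambda, lower.tail = FALSE)
}

# TRUE when any margin of the table is empty (a constant column).
degenerate_margin <- function(a, b, c, d) {
  (a + b) == 0 | (c + d) == 0 | (a + c) == 0 | (b + d) == 0
}
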