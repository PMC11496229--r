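#' Fourfold (2x2) table for an ordered variable pair
#'
#' Counts of the joint outcomes of a directed pair (A, B):
#' `a` = both present, `b` = A present and B absent (the counterexamples
#' of "A implies B"), `c` = A absent and B present (the counterexamples of
#' "B implies A"), `d` = both absent. Everything downstream — the
#' implication index, its bootstrap distribution, the counterexample
#' intensity — is a function of this table.
#'
#' @param a,b,c,d non-negative integer cell counts; `a + b + c + d >= 1`.
#' @param labels length-2 character vector naming A and B.
#' @return An object of class `fourfold`.
#' @export
fourfold <- function(a, b, c, d, labels = c("A", "B")) {
  cnt <- c(a, b, c, d)
  if (length(cnt) != 4L || any(is.na(cnt)) || any(cnt < 0) ||
      any(cnt != round(cnt)))
    stop("cell counts must be non-negative integers")
  if (sum(cnt) < 1) stop("table total must be at least 1")
  structure(list(a = as.integer(a), b = as.integer(b), c = as.integer(c),
                 d = as.integer(d), n = as.integer(sum(cnt)),
                 labels = as.character(labels)),
            class = "fourfold")
}

#' @export
print.fourfold <- function(x, ...) {
  A <- x$labels[1]; B <- x$labels[2]
  m <- matrix(c(x$a, x$b, x$a + x$b,
                x$c, x$d, x$c + x$d,
                x$a + x$c, x$b + x$d, x$n),
              nrow = 3, byrow = TRUE,
              dimnames = list(c(paste0(A, "=1"), paste0(A, "=0"), "total"),
                              c(paste0(B, "=1"), paste0(B, "=0"), "total")))
  cat(sprintf("<fourfold> %s vs %s (n = %d)\n", A, B, x$n))
  print(m)
  invisible(x)
}

#' Cross-tabulate two outcomes of a matrix
#'
#' Builds the [fourfold()] table of an ordered pair. Rows with a missing
#' value in either column are excluded (a no-op after
#' [complete_case_filter()]). Swapping the roles of A and B transposes
#' the table: `(a, b, c, d)` becomes `(a, c, b, d)`.
#'
#' @param m an [outcome_matrix()].
#' @param A,B outcome labels; must differ.
#' @return A [fourfold()] table.
#' @export
crosstab <- function(m, A, B) {
  stopifnot(inherits(m, "outcome_matrix"))
  if (identical(A, B)) stop("A and B must be different outcomes")
  if (!all(c(A, B) %in% m$outcome_names))
    stop("unknown outcome(s): ",
         paste(setdiff(c(A, B), m$outcome_names), collapse = ", "))
  x <- m$values[, A]; y <- m$values[, B]
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  fourfold(sum(x & y), sum(x & !y), sum(!x & y), sum(!x & !y),
           labels = c(A, B))
}

#' Jeffreys-smoothed cell probabilities
#'
#' Adds a pseudo-count `alpha` to every cell before normalizing, so all
#' cell probabilities and margins are strictly positive and log-odds
#' quantities stay finite even with empty cells:
#' `pi_ij = (n_ij + alpha) / (n + 4 alpha)`.
#'
#' @param t a [fourfold()] table.
#' @param alpha per-cell pseudo-count, strictly positive. The default 0.5
#'   is the Jeffreys choice.
#' @return An object of class `smoothed_probs`: cell probabilities
#'   `p11, p10, p01, p00`, margins `p1., p0., p.1, p.0`, and `alpha`.
#' @export
smooth_table <- function(t, alpha = 0.5) {
  stopifnot(inherits(t, "fourfold"))
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) || alpha <= 0)
    stop("`alpha` must be a positive pseudo-count")
  den <- t$n + 4 * alpha
  p <- list(p11 = (t$a + alpha) / den, p10 = (t$b + alpha) / den,
            p01 = (t$c + alpha) / den, p00 = (t$d + alpha) / den)
  p$`p1.` <- p$p11 + p$p10
  p$`p0.` <- p$p01 + p$p00
  p$`p.1` <- p$p11 + p$p01
  p$`p.0` <- p$p10 + p$p00
  p$alpha <- alpha
  class(p) <- "smoothed_probs"
  p
}

#' @export
print.smoothed_probs <- function(x, ...) {
  cat(sprintf("<smoothed_probs> alpha = %g\n", x$alpha))
  cat(sprintf("  p11=%.4f p10=%.4f p01=%.4f p00=%.4f\n",
              x$p11, x$p10, x$p01, x$p00))
  cat(sprintf("  margins: p1.=%.4f p0.=%.4f p.1=%.4f p.0=%.4f\n",
              x$`p1.`, x$`p0.`, x$`p.1`, x$`p.0`))
  invisible(x)
}
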