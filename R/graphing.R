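#' Classify unordered pairs by their implication pattern
#'
#' Joins the two directed results of every unordered pair and assigns a
#' category: `reciprocal` (both directions significant with positive
#' index), `forward_only` (only A to B), `backward_only` (only B to A),
#' or `none`. The forward direction is the pair ordered as the outcomes
#' first appear in `results`. A significant negative index counts as
#' evidence against an implication and never as an implication edge.
#'
#' @param results a `sia_results` data frame containing both directions of
#'   every unordered pair (as produced by [analyze_all_pairs()]); a
#'   `stratum` column with several levels is classified per stratum.
#' @return A data frame with one row per unordered pair (and stratum):
#'   `source`, `target`, `stratum`, `category`, `iota_forward`,
#'   `iota_backward`, `sig_forward`, `sig_backward`.
#' @export
classify_pairs <- function(results) {
  stopifnot(is.data.frame(results))
  if (is.null(results$stratum)) results$stratum <- ""
  out <- lapply(split(results, results$stratum), classify_one_stratum)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

classify_one_stratum <- function(results) {
  labs <- unique(c(rbind(results$source, results$target)))
  prs <- which(upper.tri(diag(length(labs))), arr.ind = TRUE)
  key <- paste(results$source, results$target, sep = "\r")
  rows <- lapply(seq_len(nrow(prs)), function(k) {
    A <- labs[prs[k, "row"]]; B <- labs[prs[k, "col"]]
    fwd <- match(paste(A, B, sep = "\r"), key)
    bwd <- match(paste(B, A, sep = "\r"), key)
    if (is.na(fwd) || is.na(bwd))
      stop(sprintf("missing direction for pair (%s, %s)", A, B))
    sf <- results$significant[fwd] && results$iota[fwd] > 0
    sb <- results$significant[bwd] && results$iota[bwd] > 0
    category <- if (sf && sb) "reciprocal" else if (sf) "forward_only"
                else if (sb) "backward_only" else "none"
    data.frame(source = A, target = B, stratum = results$stratum[fwd],
               category = category,
               iota_forward = results$iota[fwd],
               iota_backward = results$iota[bwd],
               sig_forward = sf, sig_backward = sb,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Build the directed implication graph
#'
#' Nodes are the outcomes (including isolated ones); directed edges are
#' exactly the significant results with positive index, weighted by the
#' index point estimate and carrying the confidence interval.
#'
#' @param results a `sia_results` data frame from a single analysis (one
#'   stratum; subset first for stratified results).
#' @return An object of class `implication_graph`: a list with `nodes`
#'   (character vector) and `edges` (data frame `source, target, iota,
#'   ci_low, ci_high`).
#' @export
build_graph <- function(results) {
  stopifnot(is.data.frame(results))
  if (!is.null(results$stratum) && length(unique(results$stratum)) > 1)
    stop("results span several strata; subset to one stratum first")
  nodes <- unique(c(rbind(results$source, results$target)))
  keep <- results$significant & results$iota > 0
  edges <- results[keep, c("source", "target", "iota", "ci_low", "ci_high")]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "implication_graph")
}

#' @export
print.implication_graph <- function(x, ...) {
  cat(sprintf("<implication_graph> %d nodes, %d directed edges\n",
              length(x$nodes), nrow(x$edges)))
  if (nrow(x$edges))
    for (i in seq_len(nrow(x$edges)))
      cat(sprintf("  %s -> %s (iota = %.3f)\n",
                  x$edges$source[i], x$edges$target[i], x$edges$iota[i]))
  invisible(x)
}

#' Out-degrees of an implication graph
#' @param g an [build_graph()] result.
#' @return Named integer vector over all nodes.
#' @export
out_degree <- function(g) {
  stopifnot(inherits(g, "implication_graph"))
  deg <- table(factor(g$edges$source, levels = g$nodes))
  stats::setNames(as.integer(deg), g$nodes)
}

#' Export an implication graph as DOT or JSON text
#'
#' DOT output is a `digraph` with every node declared (so isolated
#' outcomes render) and edge labels
#' `"ι=<value> [<ci_low>, <ci_high>]"` at 3 decimals, ready for
#' `dot -Tsvg`. JSON output has a `nodes` array and an `edges` array of
#' `{source, target, iota, ci_low, ci_high}` objects and round-trips
#' through any JSON parser.
#'
#' @param g an `implication_graph`.
#' @param format `"dot"` or `"json"`.
#' @return A single character string.
#' @export
export_graph <- function(g, format = c("dot", "json")) {
  stopifnot(inherits(g, "implication_graph"))
  format <- match.arg(format)
  if (format == "dot") {
    lines <- c("digraph implication {",
               sprintf("  \"%s\";", g$nodes))
    if (nrow(g$edges))
      lines <- c(lines, sprintf(
        "  \"%s\" -> \"%s\" [label=\"\u03b9=%.3f [%.3f, %.3f]\"];",
        g$edges$source, g$edges$target,
        g$edges$iota, g$edges$ci_low, g$edges$ci_high))
    paste0(paste(c(lines, "}"), collapse = "\n"), "\n")
  } else {
    edges <- if (nrow(g$edges)) g$edges else
      data.frame(source = character(), target = character(),
                 iota = numeric(), ci_low = numeric(), ci_high = numeric())
    jsonlite::toJSON(list(nodes = g$nodes, edges = edges),
                     dataframe = "rows", auto_unbox = FALSE, digits = NA,
                     pretty = TRUE)
  }
}
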