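#' Score the perturbation of a two-layer network
#'
#' The full scoring pipeline in one call: match the expression table to the
#' network and renormalize downstream weights, build the Laplacian system,
#' infer differential backbone values, compute the perturbation score with
#' its spectral envelope, a CLT confidence interval (when per-gene variances
#' are available), the O and K permutation statistics, and the leading-node
#' decomposition.
#'
#' @param expr Data frame with columns `gene`, `log2fc` and optionally
#'   `variance`.
#' @param network A [two_layer_network()] (or a path readable by
#'   [read_network()]).
#' @param B Permutations per companion statistic (default 500); `0` skips
#'   both permutation tests.
#' @param level Confidence level for the score interval (default 0.95).
#' @param leading_threshold Cumulative fraction defining the leading nodes
#'   (default 0.8).
#' @param seed Optional integer seed governing both permutation tests.
#' @param o_pool Passed to [o_statistic()].
#' @param k_degree_preserving Passed to [k_statistic()].
#' @param largest_component If `TRUE`, a disconnected backbone is reduced to
#'   its largest component (with a warning) instead of failing.
#' @return An object of class `npa`: score, `ci`, `variance`, `bounds`,
#'   `contributions` (tibble with leading flags), `o` and `k`
#'   (`npa_perm` objects or NULL), `profile`, `system`, `network`.
#' @examples
#' expr <- tibble::tibble(gene = c("g1", "g2"), log2fc = c(1, 1),
#'                        variance = 0.01)
#' fit <- npa(expr, toy_network(), B = 20, seed = 1)
#' fit
#' glance(fit)
#' @export
npa <- function(expr, network, B = 500, level = 0.95,
                leading_threshold = 0.8, seed = NULL,
                o_pool = c("network", "all_measured"),
                k_degree_preserving = FALSE, largest_component = FALSE) {
  o_pool <- match.arg(o_pool)
  if (is.character(network)) network <- read_network(network)
  stopifnot(inherits(network, "two_layer_network"))
  expr <- tibble::as_tibble(expr)

  if (largest_component) network <- largest_backbone_component(network)
  net <- normalize_downstream_weights(network, expression_genes = expr$gene)
  sys <- build_laplacians(net)

  has_var <- "variance" %in% names(expr)
  profile <- if (has_var) backbone_covariance(sys, expr)
             else infer_backbone_values(sys, expr)
  score <- topo_npa_score(sys, profile)
  bounds <- score_bounds(sys, profile)
  variance <- if (has_var) score_variance(sys, profile) else NA_real_
  ci <- if (has_var) confidence_interval(score, variance, level)
        else c(lower = NA_real_, upper = NA_real_)

  contributions <- if (score > 0) {
    node_contributions(sys, profile, leading_threshold)
  } else {
    tibble::tibble(node = sys$backbone, contribution = NA_real_,
                   direction = "0", rank = seq_along(sys$backbone),
                   cumulative = NA_real_, leading = FALSE)
  }

  o <- k <- NULL
  if (B > 0) {
    o <- o_statistic(sys, expr, B = B, seed = seed, pool = o_pool)
    k <- k_statistic(net, expr, B = B, seed = if (is.null(seed)) NULL
                     else seed + 1L,
                     degree_preserving = k_degree_preserving)
  }

  structure(
    list(score = score, ci = ci, variance = variance, level = level,
         bounds = bounds, contributions = contributions, o = o, k = k,
         profile = profile, system = sys, network = net,
         leading_threshold = leading_threshold),
    class = "npa"
  )
}

#' @export
print.npa <- function(x, ...) {
  cat("<npa> score =", format(x$score, digits = 4),
      "(squared log2FC per backbone edge)\n")
  if (!is.na(x$variance)) {
    cat("  ", 100 * x$level, "% CI [", format(x$ci[["lower"]], digits = 4),
        ", ", format(x$ci[["upper"]], digits = 4), "]",
        if (x$ci[["lower"]] > 0) " *" else "", "\n", sep = "")
  }
  if (!is.null(x$o)) {
    cat("  O p =", format(x$o$pvalue, digits = 4),
        " K p =", format(x$k$pvalue, digits = 4),
        paste0("(B = ", x$o$B, ")"), "\n")
    cat("  specificity:", significance_label(x), "\n")
  }
  lead <- x$contributions$node[x$contributions$leading]
  cat("  leading nodes (", round(100 * x$leading_threshold), "%): ",
      paste(head(lead, 8), collapse = ", "),
      if (length(lead) > 8) ", ..." else "", "\n", sep = "")
  invisible(x)
}

# Report marker in the style of perturbation heatmaps: '*' for a CI above
# zero, 'o'/'k' for permutation p < 0.05 (uppercase) or < 0.1 (lowercase).
significance_label <- function(x) {
  marks <- character(0)
  if (!is.na(x$variance) && x$ci[["lower"]] > 0) marks <- c(marks, "*")
  mark1 <- function(p, ch) {
    if (p < 0.05) toupper(ch) else if (p < 0.1) ch else "."
  }
  if (!is.null(x$o)) {
    marks <- c(marks, mark1(x$o$pvalue, "o"), mark1(x$k$pvalue, "k"))
  }
  lab <- paste(marks, collapse = "")
  if (!is.null(x$o) && x$o$pvalue < 0.05 && x$k$pvalue < 0.05) {
    paste0(lab, " (specifically perturbed)")
  } else lab
}
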