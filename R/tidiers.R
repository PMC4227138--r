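#' Tidy an npa fit into its contribution table
#'
#' @param x An [npa()] object.
#' @param ... Unused.
#' @return Tibble of per-node results: `node`, `value` (inferred
#'   differential backbone value), `contribution` (percent of the score),
#'   `direction`, `rank`, `cumulative`, `leading`.
#' @export
tidy.npa <- function(x, ...) {
  vals <- tibble::tibble(node = x$profile$node,
                         value = unname(x$profile$value))
  dplyr::arrange(dplyr::left_join(x$contributions, vals, by = "node"),
                 .data$rank)[, c("node", "value", "contribution",
                                 "direction", "rank", "cumulative",
                                 "leading")]
}

#' One-row summary of an npa fit
#'
#' @param x An [npa()] object.
#' @param ... Unused.
#' @return A one-row tibble: score, confidence limits, score variance,
#'   spectral bounds, permutation p-values, leading-node count, network
#'   size, and the significance marker.
#' @export
glance.npa <- function(x, ...) {
  tibble::tibble(
    score = x$score,
    ci_lower = x$ci[["lower"]], ci_upper = x$ci[["upper"]],
    variance = x$variance,
    bound_lower = x$bounds[["lower"]], bound_upper = x$bounds[["upper"]],
    o_pvalue = if (is.null(x$o)) NA_real_ else x$o$pvalue,
    k_pvalue = if (is.null(x$k)) NA_real_ else x$k$pvalue,
    n_leading = sum(x$contributions$leading),
    n_backbone = length(x$system$backbone),
    n_genes = length(x$system$transcript),
    signif = significance_label(x)
  )
}

#' Tidy a permutation result
#' @param x An `npa_perm` object.
#' @param ... Unused.
#' @return Tibble `draw`, `score` of the null distribution.
#' @export
tidy.npa_perm <- function(x, ...) {
  tibble::tibble(draw = seq_along(x$null_scores), score = x$null_scores)
}

#' @export
glance.npa_perm <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, observed = x$observed_score,
                 pvalue = x$pvalue, B = x$B, redraws = x$redraws)
}

#' Tidy a sample-backbone matrix into long form
#' @param x A [map_samples_to_backbone()] result.
#' @param ... Unused.
#' @return Tibble `node`, `sample`, `value`.
#' @export
tidy.sample_backbone_matrix <- function(x, ...) {
  tibble::as_tibble(x$values, rownames = "node") |>
    tidyr::pivot_longer(-"node", names_to = "sample", values_to = "value")
}

#' Contribution bar chart of an npa fit
#'
#' Nodes in rank order, bar length = percent contribution to the score,
#' fill = direction of the inferred backbone value, leading nodes opaque.
#'
#' @param object An [npa()] object.
#' @param top Show at most this many top-ranked nodes (default 25).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot npa
#' @export
autoplot.npa <- function(object, top = 25, ...) {
  tab <- head(tidy(object), top)
  ggplot2::ggplot(tab, ggplot2::aes(
    x = .data$contribution,
    y = stats::reorder(.data$node, -.data$rank),
    fill = .data$direction, alpha = .data$leading)) +
    ggplot2::geom_col() +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.35),
                                guide = "none") +
    ggplot2::scale_fill_manual(values = c(`+` = "#c0392b", `-` = "#2980b9",
                                          `0` = "grey60")) +
    ggplot2::labs(x = "contribution to score (%)", y = NULL,
                  fill = "direction",
                  title = sprintf("NPA = %.3g %s", object$score,
                                  significance_label(object))) +
    ggplot2::theme_minimal()
}

#' Null-distribution plot of a permutation statistic
#'
#' @param object An `npa_perm` object.
#' @param ... Unused.
#' @return A ggplot object: histogram of null scores with the observed
#'   score as a vertical line.
#' @method autoplot npa_perm
#' @export
autoplot.npa_perm <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$score)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", color = "white") +
    ggplot2::geom_vline(xintercept = object$observed_score,
                        color = "#c0392b", linewidth = 1) +
    ggplot2::labs(
      title = sprintf("%s-statistic: p = %.3g (B = %d)",
                      object$statistic, object$pvalue, object$B),
      x = "null score", y = "count") +
    ggplot2::theme_minimal()
}

#' Principal-component view of sample backbone values
#'
#' @param object A [map_samples_to_backbone()] result.
#' @param labels Optional tibble `sample`, `class` to color points.
#' @param ... Unused.
#' @return A ggplot object of the first two PCs of the samples in backbone
#'   space.
#' @method autoplot sample_backbone_matrix
#' @export
autoplot.sample_backbone_matrix <- function(object, labels = NULL, ...) {
  pc <- stats::prcomp(t(object$values), center = TRUE, scale. = FALSE)
  tab <- tibble::tibble(sample = object$samples,
                        PC1 = pc$x[, 1],
                        PC2 = if (ncol(pc$x) > 1) pc$x[, 2] else 0)
  if (!is.null(labels)) {
    tab <- dplyr::left_join(tab, tibble::as_tibble(labels), by = "sample")
    p <- ggplot2::ggplot(tab, ggplot2::aes(.data$PC1, .data$PC2,
                                           color = .data$class))
  } else {
    p <- ggplot2::ggplot(tab, ggplot2::aes(.data$PC1, .data$PC2))
  }
  p + ggplot2::geom_point(size = 2) +
    ggplot2::labs(title = "samples in backbone space") +
    ggplot2::theme_minimal()
}
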