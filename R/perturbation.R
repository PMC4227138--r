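#' Infer differential backbone values from gene fold-changes
#'
#' The backbone values f are the unique minimizer of the signed smoothness
#' objective
#' \deqn{\sum_{x \to y} w(x,y) (f(x) - \sigma(x \to y) f(y))^2}
#' subject to f equalling the measured log2 fold-changes on the transcript
#' layer -- a Dirichlet boundary-value problem on the graph. Its closed form
#' is \eqn{f = -L_3^{-1} L_2 \beta}, computed here through the cached
#' Cholesky factorization of `L3` (never an explicit inverse).
#'
#' @param sys A [build_laplacians()] system.
#' @param expr A data frame with columns `gene`, `log2fc` and optionally
#'   `variance` (per-gene sampling variance of the fold-change, e.g. from a
#'   moderated linear model). Must cover every transcript node of `sys`;
#'   gene matching / weight renormalization is assumed already done via
#'   [normalize_downstream_weights()].
#' @return A `backbone_profile`: list with `node` (backbone order), `value`
#'   (inferred differential values, same units as `log2fc`) and
#'   `covariance` (NULL here; see [backbone_covariance()]).
#' @examples
#' sys <- build_laplacians(normalize_downstream_weights(toy_network()))
#' expr <- tibble::tibble(gene = c("g1", "g2"), log2fc = c(1, 1))
#' infer_backbone_values(sys, expr)$value # c(1, 1)
#' @export
infer_backbone_values <- function(sys, expr) {
  beta <- match_expression(sys, expr)
  f <- as.numeric(-solve_L3(sys, as.numeric(sys$L2 %*% beta)))
  backbone_profile(sys$backbone, f)
}

match_expression <- function(sys, expr, need_variance = FALSE) {
  expr <- tibble::as_tibble(expr)
  stopifnot(all(c("gene", "log2fc") %in% names(expr)))
  if (anyDuplicated(expr$gene)) abort("duplicate gene ids in expression table")
  idx <- match(sys$transcript, expr$gene)
  if (anyNA(idx)) {
    miss <- sys$transcript[is.na(idx)]
    abort(paste0("expression table missing ", length(miss),
                 " transcript gene(s): ",
                 paste(head(miss, 10), collapse = ", "),
                 if (length(miss) > 10) ", ..." else ""))
  }
  beta <- expr$log2fc[idx]
  if (any(!is.finite(beta))) abort("non-finite log2fc values")
  if (need_variance) {
    if (!"variance" %in% names(expr)) {
      abort("expression table has no `variance` column")
    }
    v <- expr$variance[idx]
    if (any(!is.finite(v) | v < 0)) abort("variances must be finite and >= 0")
    attr(beta, "variance") <- v
  }
  setNames(beta, sys$transcript)
}

backbone_profile <- function(node, value, covariance = NULL) {
  stopifnot(length(node) == length(value))
  if (!is.null(covariance)) {
    stopifnot(nrow(covariance) == length(node))
    if (max(abs(covariance - t(covariance))) > 1e-10) {
      abort("covariance not symmetric")
    }
  }
  structure(list(node = node, value = setNames(as.numeric(value), node),
                 covariance = covariance),
            class = "backbone_profile")
}

#' @export
print.backbone_profile <- function(x, ...) {
  cat("<backbone_profile> ", length(x$node), " nodes",
      if (!is.null(x$covariance)) ", with covariance" else "", "\n", sep = "")
  print(utils::head(tibble::tibble(node = x$node, value = x$value), 10))
  invisible(x)
}

profile_values <- function(sys, profile) {
  if (inherits(profile, "backbone_profile")) {
    if (!identical(profile$node, sys$backbone)) {
      v <- profile$value[sys$backbone]
      if (anyNA(v)) abort("profile does not cover the backbone of this system")
      return(as.numeric(v))
    }
    return(as.numeric(profile$value))
  }
  f <- as.numeric(profile)
  if (length(f) != length(sys$backbone)) {
    abort("profile length does not match backbone size")
  }
  f
}

#' Network perturbation amplitude score
#'
#' The score is the edge-normalized "energy" of the inferred backbone
#' values on the sign-flipped backbone:
#' \deqn{NPA = \frac{1}{C} \sum_{x \to y} w(x,y)(f(x) + \sigma(x \to y) f(y))^2
#'       = \frac{1}{C} f^T Q f,}
#' summed over backbone-backbone edges. Each well-accommodated signed edge
#' between two strongly moved nodes contributes a large term; normalizing by
#' the edge count C makes scores comparable across networks of different
#' size. Units: squared log2 fold-change per backbone edge.
#'
#' The quadratic-form and explicit edge-sum evaluations are both computed
#' and asserted equal (tolerance `1e-10` relative), a cheap structural
#' self-check of the assembled matrices.
#'
#' @param sys A [build_laplacians()] system.
#' @param profile A `backbone_profile` or numeric vector over the backbone.
#' @return Non-negative scalar score.
#' @examples
#' sys <- build_laplacians(normalize_downstream_weights(toy_network()))
#' topo_npa_score(sys, c(1, 1)) # 4
#' @export
topo_npa_score <- function(sys, profile) {
  f <- profile_values(sys, profile)
  quad <- as.numeric(crossprod(f, sys$Q %*% f)) / sys$C
  edge <- score_edge_sum(sys, f)
  if (abs(quad - edge) > 1e-10 * max(1, abs(quad))) {
    abort("internal inconsistency: quadratic form and edge sum disagree")
  }
  max(quad, 0)
}

score_edge_sum <- function(sys, f) {
  eb <- sys$backbone_edge_table
  i <- match(eb$source, sys$backbone)
  j <- match(eb$target, sys$backbone)
  sum(eb$weight * (f[i] + eb$sign * f[j])^2) / sys$C
}

#' Spectral envelope of the score
#'
#' Rayleigh-quotient bounds: for backbone values f,
#' \deqn{\frac{\|f\|^2}{C}\lambda_{min}(Q) \le NPA \le
#'       \frac{\|f\|^2}{C}\lambda_{max}(Q).}
#' The lower bound vanishes exactly when the sign-flipped backbone is
#' balanced (see [is_balanced()]); the upper bound is attained when f is a
#' top eigenvector of Q -- the "high-energy" configurations of the network.
#'
#' @inheritParams topo_npa_score
#' @return Named numeric `c(lower, upper)`.
#' @export
score_bounds <- function(sys, profile) {
  f <- profile_values(sys, profile)
  n2 <- sum(f^2)
  ev <- sys$Q_eigenvalues
  c(lower = n2 * max(min(ev), 0) / sys$C, upper = n2 * max(ev) / sys$C)
}

#' Decompose the score into per-node contributions
#'
#' Writing the score as \eqn{\frac{1}{C}\sum_y (Qf)(y) f(y)}, node y
#' contributes \eqn{100 \cdot \frac{(Qf)(y) f(y) / C}{NPA}} percent.
#' Contributions sum to 100 exactly (individual entries may be negative:
#' a node can locally oppose the signed structure). Nodes are ranked by
#' descending contribution, ties broken by node id, and the minimal ranked
#' prefix reaching the cumulative threshold is flagged as the leading nodes.
#'
#' @inheritParams topo_npa_score
#' @param cumulative_threshold Fraction of the score the leading set must
#'   reach (default 0.8). Negative contributions are accumulated in rank
#'   order, preserving the sum-to-100 identity.
#' @return A tibble `node`, `contribution` (percent), `direction`
#'   (sign of f at the node), `rank`, `cumulative`, `leading`.
#' @examples
#' sys <- build_laplacians(normalize_downstream_weights(toy_network()))
#' node_contributions(sys, c(1, 1)) # 50% each, both leading
#' @export
node_contributions <- function(sys, profile, cumulative_threshold = 0.8) {
  f <- profile_values(sys, profile)
  score <- topo_npa_score(sys, f)
  if (score <= 0) abort("no perturbation to decompose (score is zero)")
  contrib <- 100 * as.numeric(sys$Q %*% f) * f / (sys$C * score)
  out <- tibble::tibble(
    node = sys$backbone,
    contribution = contrib,
    direction = ifelse(f > 0, "+", ifelse(f < 0, "-", "0"))
  )
  out <- dplyr::arrange(out, dplyr::desc(.data$contribution), .data$node)
  out$rank <- seq_len(nrow(out))
  leading_nodes(out, cumulative_threshold)
}

#' Flag the leading nodes of a ranked contribution table
#'
#' @param contributions A ranked contribution table as produced by
#'   [node_contributions()] (columns `node`, `contribution`, `rank`).
#' @param cumulative_threshold Fraction in (0, 1]; default 0.8.
#' @return The table with `cumulative` and logical `leading` columns; the
#'   leading set is the minimal prefix whose cumulative contribution reaches
#'   `100 * cumulative_threshold`.
#' @export
leading_nodes <- function(contributions, cumulative_threshold = 0.8) {
  if (!is.numeric(cumulative_threshold) || length(cumulative_threshold) != 1 ||
      cumulative_threshold <= 0 || cumulative_threshold > 1) {
    abort("cumulative_threshold must be a single number in (0, 1]")
  }
  stopifnot(all(c("node", "contribution", "rank") %in% names(contributions)))
  tab <- dplyr::arrange(tibble::as_tibble(contributions), .data$rank)
  tab$cumulative <- cumsum(tab$contribution)
  target <- 100 * cumulative_threshold
  hit <- which(tab$cumulative >= target - 1e-9)
  cutoff <- if (length(hit) == 0) nrow(tab) else hit[[1]]
  tab$leading <- tab$rank <= cutoff
  tab
}
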