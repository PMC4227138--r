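#' Covariance of the inferred backbone values
#'
#' Under the usual two-group comparison with homoscedastic groups, the
#' covariance between per-gene fold-changes vanishes (no second-order
#' treatment effect) and \eqn{\beta \sim N(\mu, diag(var \beta_i))}. The
#' backbone values are the linear image \eqn{f = M\beta} with
#' \eqn{M = -L_3^{-1} L_2}, so
#' \deqn{\Sigma_2 = M \, diag(var\,\beta) \, M^T.}
#'
#' @param sys A [build_laplacians()] system.
#' @param expr Expression table with `gene`, `log2fc` and `variance`
#'   columns covering the transcript layer.
#' @return A `backbone_profile` with `value` = inferred backbone means and
#'   `covariance` = \eqn{\Sigma_2} (symmetric PSD).
#' @examples
#' sys <- build_laplacians(normalize_downstream_weights(toy_network()))
#' expr <- tibble::tibble(gene = c("g1", "g2"), log2fc = c(1, 1), variance = 1)
#' backbone_covariance(sys, expr)$covariance # (1/9) [[5,4],[4,5]]
#' @export
backbone_covariance <- function(sys, expr) {
  beta <- match_expression(sys, expr, need_variance = TRUE)
  v <- attr(beta, "variance")
  M <- backbone_transform(sys)
  Sigma2 <- M %*% (v * t(M))
  Sigma2 <- (Sigma2 + t(Sigma2)) / 2
  f <- as.numeric(M %*% as.numeric(beta))
  backbone_profile(sys$backbone, f, covariance = Sigma2)
}

#' Variance of the perturbation score
#'
#' For \eqn{h \sim N(\mu_2, \Sigma_2)} the quadratic form \eqn{h^T Q h} has
#' \deqn{var(h^T Q h) = 2\,tr(Q\Sigma_2 Q\Sigma_2) + 4\,\mu_2^T Q\Sigma_2 Q\mu_2,}
#' and the score is \eqn{h^T Q h / C}, so its variance carries a
#' \eqn{1/C^2} factor.
#'
#' @param sys A [build_laplacians()] system.
#' @param profile A `backbone_profile` carrying a covariance (from
#'   [backbone_covariance()]).
#' @return Non-negative scalar variance of the score.
#' @export
score_variance <- function(sys, profile) {
  if (!inherits(profile, "backbone_profile") || is.null(profile$covariance)) {
    abort("profile has no covariance; compute it with backbone_covariance()")
  }
  mu <- profile_values(sys, profile)
  QS <- sys$Q %*% profile$covariance
  v <- (2 * sum(QS * t(QS)) +
          4 * as.numeric(crossprod(mu, QS %*% (sys$Q %*% mu)))) / sys$C^2
  max(v, 0)
}

#' Asymptotic confidence interval for the score
#'
#' A central-limit-theorem interval \eqn{score \pm z_{(1+level)/2}\sqrt{var}}.
#' The lower limit is deliberately not clipped at zero: a lower limit above
#' zero is the criterion for the perturbation being significant against
#' experimental variation.
#'
#' @param score Observed score.
#' @param variance Score variance from [score_variance()].
#' @param level Two-sided confidence level in (0, 1); default 0.95.
#' @return Named numeric `c(lower, upper)`.
#' @export
confidence_interval <- function(score, variance, level = 0.95) {
  if (!is.numeric(variance) || variance < 0) abort("variance must be >= 0")
  if (!is.numeric(level) || level <= 0 || level >= 1) {
    abort("level must be in (0, 1)")
  }
  z <- qnorm((1 + level) / 2)
  c(lower = score - z * sqrt(variance), upper = score + z * sqrt(variance))
}

permutation_result <- function(statistic, observed, null_scores, B, seed,
                               redraws = 0L) {
  pvalue <- (1 + sum(null_scores >= observed)) / (B + 1)
  structure(
    list(statistic = statistic, observed_score = observed,
         null_scores = null_scores, pvalue = pvalue, B = B, seed = seed,
         redraws = redraws),
    class = "npa_perm"
  )
}

#' @export
print.npa_perm <- function(x, ...) {
  cat("<npa_perm> ", x$statistic, "-statistic: observed = ",
      format(x$observed_score, digits = 4), ", p = ",
      format(x$pvalue, digits = 4), " (B = ", x$B,
      if (x$redraws > 0) paste0(", ", x$redraws, " redraws") else "",
      ")\n", sep = "")
  invisible(x)
}

#' O-statistic: downstream-gene assignment permutation test
#'
#' Tests whether the placement of the measured fold-changes on the
#' transcript layer matters for the score, against the null that it does
#' not. Each draw reassigns the observed log2 fold-change values uniformly
#' at random across the transcript-layer positions of the network (the
#' network itself is untouched), backbone values are re-inferred, and the
#' score recomputed. The permutation p-value uses the add-one rule
#' \eqn{(1 + \#\{null \ge observed\})/(B + 1)}, so it is never exactly zero.
#'
#' @param sys A [build_laplacians()] system.
#' @param expr Expression table covering the transcript layer.
#' @param B Number of permutations (default 500).
#' @param seed Optional integer seed for reproducibility.
#' @param pool `"network"` (default) permutes the fold-changes of the
#'   network's own transcript nodes; `"all_measured"` draws each
#'   permutation's values from the full measured gene pool in `expr`.
#' @return An `npa_perm` object (observed score, null scores, p-value).
#' @export
o_statistic <- function(sys, expr, B = 500, seed = NULL,
                        pool = c("network", "all_measured")) {
  pool <- match.arg(pool)
  if (B < 1) abort("B must be >= 1")
  nt <- length(sys$transcript)
  if (nt < 2) abort("permutation degenerate: fewer than 2 transcript nodes")
  if (!is.null(seed)) set.seed(seed)

  beta <- as.numeric(match_expression(sys, expr))
  M <- backbone_transform(sys)
  observed <- topo_npa_score(sys, as.numeric(M %*% beta))

  source_pool <- if (pool == "network") beta else {
    x <- tibble::as_tibble(expr)$log2fc
    x[is.finite(x)]
  }
  P <- vapply(seq_len(B), function(b) {
    if (pool == "network") sample(source_pool)
    else sample(source_pool, nt, replace = FALSE)
  }, numeric(nt))
  Fmat <- M %*% P
  null_scores <- colSums(Fmat * (sys$Q %*% Fmat)) / sys$C
  permutation_result("O", observed, as.numeric(null_scores), B, seed)
}

#' K-statistic: backbone rewiring permutation test
#'
#' Tests whether the cause-and-effect wiring of the backbone matters for
#' the score. Each draw replaces the backbone edge set with a uniformly
#' random simple edge set of the same size C over the same backbone nodes
#' (no self-loops, no duplicates), reassigns the original multiset of edge
#' signs (and weights) to the new edges in random order, and keeps all
#' transcript edges fixed. Backbone values are re-inferred under the
#' rewired Laplacian and scored with the ORIGINAL matrix Q, whose largest
#' eigenvalue -- the spectral ceiling of the score -- is thereby held fixed
#' across draws. Draws whose rewired backbone is disconnected or numerically
#' singular are rejected and redrawn (the count is reported).
#'
#' @param net A validated, weight-normalized [two_layer_network()].
#' @param expr Expression table covering the transcript layer.
#' @param B Number of rewirings (default 500).
#' @param seed Optional integer seed.
#' @param degree_preserving If `TRUE`, rewire by repeated double-edge swaps
#'   (preserving the undirected degree sequence) instead of uniform
#'   resampling of the edge set.
#' @param max_attempts Redraw budget per accepted draw.
#' @return An `npa_perm` object.
#' @export
k_statistic <- function(net, expr, B = 500, seed = NULL,
                        degree_preserving = FALSE, max_attempts = 1000) {
  if (B < 1) abort("B must be >= 1")
  sys <- build_laplacians(net)
  if (sys$C < 2) {
    warn("backbone has a single edge: rewiring is degenerate and p = 1")
  }
  if (!is.null(seed)) set.seed(seed)

  beta <- as.numeric(match_expression(sys, expr))
  observed <- topo_npa_score(sys, infer_backbone_values(sys, expr))

  nb <- length(sys$backbone)
  eb <- sys$backbone_edge_table
  i0 <- match(eb$source, sys$backbone)
  j0 <- match(eb$target, sys$backbone)
  C <- sys$C
  pair_idx <- arrayInd(which(upper.tri(matrix(FALSE, nb, nb))), c(nb, nb))
  n_pairs <- nrow(pair_idx)
  if (!degree_preserving && n_pairs < C) {
    abort("backbone too small: fewer node pairs than edges to place")
  }

  # fixed parts of L3: transcript out-degrees on the diagonal
  tr_deg <- numeric(nb)
  et <- transcript_edges(net)
  tdt <- tapply(et$weight, match(et$source, sys$backbone), sum)
  tr_deg[as.integer(names(tdt))] <- tdt
  L2beta <- as.numeric(sys$L2 %*% beta)

  null_scores <- numeric(B)
  redraws <- 0L
  only_wiring <- !degree_preserving && n_pairs == C # unique simple graph
  for (b in seq_len(B)) {
    accepted <- FALSE
    for (att in seq_len(max_attempts)) {
      if (degree_preserving) {
        sw <- edge_swap(i0, j0, nswap = 10 * C)
        ii <- sw$i; jj <- sw$j
      } else {
        pid <- sample.int(n_pairs, C)
        ii <- pair_idx[pid, 1]
        jj <- pair_idx[pid, 2]
      }
      if (!pairs_connected(ii, jj, nb)) { redraws <- redraws + 1L; next }
      ord <- sample.int(C)
      s <- eb$sign[ord]; w <- eb$weight[ord]
      # rewired L3
      deg <- tr_deg
      ends <- c(ii, jj); wboth <- c(w, w)
      for (t in seq_along(ends)) deg[ends[t]] <- deg[ends[t]] + wboth[t]
      Ab <- matrix(0, nb, nb)
      Ab[cbind(ii, jj)] <- s * w
      L3p <- diag(deg, nb) - (Ab + t(Ab))
      Rp <- tryCatch(chol(L3p), error = function(e) NULL)
      if (is.null(Rp) || min(diag(Rp)) < 1e-8) {
        redraws <- redraws + 1L; next
      }
      f <- -backsolve(Rp, backsolve(Rp, L2beta, transpose = TRUE))
      null_scores[b] <- as.numeric(crossprod(f, sys$Q %*% f)) / C
      accepted <- TRUE
      break
    }
    if (!accepted) {
      if (only_wiring) {
        # a single admissible wiring: the null equals the observed score
        null_scores[b] <- observed
      } else {
        abort(paste0("no admissible backbone rewiring found in ",
                     max_attempts, " attempts"))
      }
    }
  }
  permutation_result("K", observed, null_scores, B, seed, redraws = redraws)
}

# does the edge list connect all n nodes? (union-find)
pairs_connected <- function(i, j, n) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (k in seq_along(i)) {
    ri <- find(i[k]); rj <- find(j[k])
    if (ri != rj) parent[ri] <- rj
  }
  length(unique(vapply(seq_len(n), find, integer(1)))) == 1
}

# double-edge swaps on the undirected backbone, keeping the degree sequence
edge_swap <- function(i, j, nswap) {
  C <- length(i)
  for (s in seq_len(nswap)) {
    ab <- sample.int(C, 2)
    a <- ab[1]; b <- ab[2]
    # swap endpoints: (i_a, j_a), (i_b, j_b) -> (i_a, j_b), (i_b, j_a)
    ni_a <- i[a]; nj_a <- j[b]; ni_b <- i[b]; nj_b <- j[a]
    if (ni_a == nj_a || ni_b == nj_b) next
    key <- paste(pmin(i, j), pmax(i, j))
    k1 <- paste(min(ni_a, nj_a), max(ni_a, nj_a))
    k2 <- paste(min(ni_b, nj_b), max(ni_b, nj_b))
    if (k1 %in% key[-c(a, b)] || k2 %in% key[-c(a, b)] || k1 == k2) next
    i[a] <- ni_a; j[a] <- nj_a; i[b] <- ni_b; j[b] <- nj_b
  }
  list(i = i, j = j)
}
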