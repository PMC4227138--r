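#' Build the Laplacian system of a two-layer network
#'
#' Assembles the matrices that drive every downstream computation. With
#' signed weighted adjacency \eqn{A_{xy} = sign(x \to y) w(x,y)} over all
#' nodes, the signed Laplacian of the underlying undirected graph is
#' \deqn{L = diag(out) + diag(in) - (A + A^T).}
#' `L3` is its backbone block (degrees include transcript edges), `L2` the
#' backbone-rows by transcript-columns block, and
#' \deqn{Q = diag(out_b) + diag(in_b) + (A_b + A_b^T)}
#' is the signed Laplacian of the sign-flipped backbone-only subgraph Gb-
#' (subscript b: backbone-backbone edges only; the sign flip turns the
#' adjacency minus into a plus). `C` counts backbone-backbone edges.
#'
#' `L3` is irreducibly diagonally dominant when the undirected backbone is
#' connected and at least one node has a downstream gene, hence invertible;
#' this is checked numerically through its condition number. `Q` is a sum of
#' per-edge positive semi-definite terms
#' \eqn{w (f(x) + \sigma f(y))^2}, hence PSD.
#'
#' @param net A validated, weight-normalized [two_layer_network()].
#' @param condition_limit Condition-number threshold above which `L3` is
#'   declared numerically singular (default `1e12`, far beyond anything a
#'   connected backbone produces; it distinguishes structural singularity
#'   from round-off).
#' @return An object of class `laplacian_system`: list with `backbone`,
#'   `transcript` (orderings fixing matrix indices), dense `L3` and `Q`,
#'   sparse `L2` (a [Matrix::sparseMatrix()]; transcript columns can number
#'   in the thousands), `C`, the backbone edge table, and a cached Cholesky
#'   factor of `L3`.
#' @examples
#' sys <- build_laplacians(normalize_downstream_weights(toy_network()))
#' sys$L3 # [[2,-1],[-1,2]]
#' sys$Q  # [[1,1],[1,1]]
#' @export
build_laplacians <- function(net, condition_limit = 1e12) {
  stopifnot(inherits(net, "two_layer_network"))
  bad <- validate_network(net)
  if (nrow(bad) > 0) {
    abort(paste0("network fails validation: ",
                 paste(bad$message, collapse = "; ")))
  }
  nb <- length(net$backbone)
  nt <- length(net$transcript)
  bidx <- setNames(seq_len(nb), net$backbone)
  tidx <- setNames(seq_len(nt), net$transcript)

  eb <- backbone_edges(net)
  et <- transcript_edges(net)
  if (nrow(eb) == 0) abort("backbone has no internal edges")

  # weighted degrees over all edges, restricted to backbone nodes
  deg <- numeric(nb)
  src_all <- bidx[net$edges$source]
  deg_tab <- tapply(net$edges$weight, src_all, sum)
  deg[as.integer(names(deg_tab))] <- deg_tab
  in_b <- tapply(eb$weight, bidx[eb$target], sum)
  deg[as.integer(names(in_b))] <- deg[as.integer(names(in_b))] + in_b

  # backbone signed adjacency (dense; at most a few hundred nodes)
  Ab <- matrix(0, nb, nb, dimnames = list(net$backbone, net$backbone))
  Ab[cbind(bidx[eb$source], bidx[eb$target])] <- eb$sign * eb$weight
  L3 <- diag(deg, nb) - (Ab + t(Ab))
  dimnames(L3) <- list(net$backbone, net$backbone)

  L2 <- Matrix::sparseMatrix(
    i = bidx[et$source], j = tidx[et$target],
    x = -et$sign * et$weight, dims = c(nb, nt),
    dimnames = list(net$backbone, net$transcript)
  )

  deg_b <- numeric(nb)
  out_b <- tapply(eb$weight, bidx[eb$source], sum)
  deg_b[as.integer(names(out_b))] <- out_b
  inn_b <- tapply(eb$weight, bidx[eb$target], sum)
  deg_b[as.integer(names(inn_b))] <- deg_b[as.integer(names(inn_b))] + inn_b
  Q <- diag(deg_b, nb) + (Ab + t(Ab))
  dimnames(Q) <- list(net$backbone, net$backbone)

  kappa_L3 <- kappa(L3, exact = nb <= 200)
  if (!is.finite(kappa_L3) || kappa_L3 > condition_limit) {
    comp <- backbone_components(net)
    abort(paste0(
      "L3 numerically singular (condition number ", format(kappa_L3, digits = 3),
      "); backbone has ", comp$n_components, " component(s) and ",
      nrow(et), " transcript edge(s)"))
  }
  if (max(abs(Q - t(Q))) > 1e-10) abort("Q not symmetric")
  ev <- eigen(Q, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(1, max(ev))) {
    abort("Q not positive semi-definite within tolerance")
  }

  structure(
    list(backbone = net$backbone, transcript = net$transcript,
         L3 = L3, L2 = L2, Q = Q, C = nrow(eb),
         backbone_edge_table = eb,
         chol_L3 = chol(L3),
         Q_eigenvalues = ev,
         kappa_L3 = kappa_L3),
    class = "laplacian_system"
  )
}

#' @export
print.laplacian_system <- function(x, ...) {
  cat("<laplacian_system>\n")
  cat("  backbone:", length(x$backbone), "nodes,", x$C, "internal edges\n")
  cat("  transcript:", length(x$transcript), "genes\n")
  cat("  cond(L3) =", format(x$kappa_L3, digits = 3),
      "  eig(Q) in [", format(min(x$Q_eigenvalues), digits = 3), ",",
      format(max(x$Q_eigenvalues), digits = 3), "]\n")
  invisible(x)
}

# Solve L3 x = b through the cached Cholesky factor (L3 is symmetric
# positive definite for a connected backbone with downstream genes).
solve_L3 <- function(sys, b) {
  backsolve(sys$chol_L3, backsolve(sys$chol_L3, b, transpose = TRUE))
}

# Dense transform matrix M = -L3^{-1} L2 (backbone x transcript), the
# data-independent linear map from fold-changes to backbone values.
backbone_transform <- function(sys) {
  M <- -solve_L3(sys, as.matrix(sys$L2))
  dimnames(M) <- list(sys$backbone, sys$transcript)
  M
}
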