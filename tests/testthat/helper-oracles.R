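# Independent brute-force oracles used across the suite. They assemble
# matrices entry-by-entry from the edge list and solve the original
# constrained problem directly, sharing no code path with the package's
# block formulas.

# full signed Laplacian over all nodes, built edge-by-edge
naive_full_laplacian <- function(net) {
  nodes <- c(net$backbone, net$transcript)
  n <- length(nodes)
  L <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (k in seq_len(nrow(net$edges))) {
    e <- net$edges[k, ]
    x <- e$source; y <- e$target; w <- e$weight; s <- e$sign
    L[x, x] <- L[x, x] + w
    L[y, y] <- L[y, y] + w
    L[x, y] <- L[x, y] - s * w
    L[y, x] <- L[y, x] - s * w
  }
  L
}

# sign-flipped backbone Laplacian, edge-by-edge
naive_Q <- function(net) {
  nb <- net$backbone
  Q <- matrix(0, length(nb), length(nb), dimnames = list(nb, nb))
  eb <- net$edges[net$edges$layer_target == "backbone", ]
  for (k in seq_len(nrow(eb))) {
    e <- eb[k, ]
    Q[e$source, e$source] <- Q[e$source, e$source] + e$weight
    Q[e$target, e$target] <- Q[e$target, e$target] + e$weight
    Q[e$source, e$target] <- Q[e$source, e$target] + e$sign * e$weight
    Q[e$target, e$source] <- Q[e$target, e$source] + e$sign * e$weight
  }
  Q
}

# equality-constrained QP: min f' L f  s.t. f on the transcript layer = beta,
# solved through the full KKT system (no block elimination)
qp_oracle_backbone <- function(net, beta) {
  L <- naive_full_laplacian(net)
  nodes <- rownames(L)
  n <- length(nodes)
  m <- length(net$transcript)
  E <- matrix(0, m, n)
  E[cbind(seq_len(m), match(net$transcript, nodes))] <- 1
  KKT <- rbind(cbind(2 * L, t(E)), cbind(E, matrix(0, m, m)))
  rhs <- c(rep(0, n), beta[net$transcript])
  sol <- solve(KKT, rhs)
  setNames(sol[match(net$backbone, nodes)], net$backbone)
}

# score by direct summation over backbone edges
naive_score <- function(net, f) {
  eb <- net$edges[net$edges$layer_target == "backbone", ]
  s <- 0
  for (k in seq_len(nrow(eb))) {
    e <- eb[k, ]
    s <- s + e$weight * (f[[e$source]] + e$sign * f[[e$target]])^2
  }
  s / nrow(eb)
}

# a small random valid network for property tests (independent knobs from
# generate_network's defaults)
random_test_network <- function(n_backbone = sample(3:10, 1),
                                max_genes = 4, p_neg = 0.4) {
  generate_network(
    n_backbone = n_backbone, edge_p = 0.3, p_neg = p_neg,
    genes_per_node = c(1, max_genes), p_no_genes = 0.2
  )
}

random_expression <- function(net, sd = 1) {
  tibble::tibble(gene = net$transcript,
                 log2fc = rnorm(length(net$transcript), sd = sd),
                 variance = runif(length(net$transcript), 0.01, 0.5))
}

transcript_weights <- function(net, node) {
  e <- net$edges
  e$weight[e$layer_target == "transcript" & e$source == node]
}

backbone_components_count <- function(net) {
  eb <- net$edges[net$edges$layer_target == "backbone", ]
  g <- igraph::graph_from_data_frame(eb[, 1:2], directed = FALSE,
                                     vertices = data.frame(name = net$backbone))
  igraph::components(g)$no
}
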