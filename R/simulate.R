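#' Generate a random two-layer network
#'
#' Builds a connected signed backbone as a uniform random spanning tree plus
#' independent extra edges, then hangs an exclusive block of downstream
#' genes off each backbone node. The defaults emulate the scale of curated
#' disease-network models: a backbone of a few dozen functional nodes, a
#' transcript layer of around a thousand genes, and a minority of backbone
#' nodes with no measured downstream genes.
#'
#' @param n_backbone Number of backbone nodes (>= 2).
#' @param edge_p Probability of each non-tree backbone pair receiving an
#'   extra edge (default 0.08).
#' @param p_neg Probability an edge sign is negative (default 0.3).
#' @param genes_per_node Length-2 integer range; each gene-bearing node
#'   draws its downstream count uniformly from it (default 15..25).
#' @param p_no_genes Fraction of backbone nodes left without downstream
#'   genes (default 0.1; at least one node always keeps genes).
#' @param balanced If `TRUE`, backbone signs are switched so the
#'   sign-flipped backbone Gb- is balanced ([is_balanced()] returns `TRUE`).
#' @param backbone_model `"tree"` (default) grows a random spanning tree and
#'   adds extra edges with probability `edge_p`; `"uniform"` draws the whole
#'   edge set uniformly among connected simple graphs with the matching
#'   expected edge count (rejection sampling on connectivity). The uniform
#'   model is the ensemble the K-statistic rewires over, which makes it the
#'   right generator for calibration studies of that test.
#' @param seed Optional integer seed; identical parameters and seed give a
#'   bit-identical network.
#' @return A [two_layer_network()] that passes [validate_network()], with
#'   unit backbone weights and unit (un-normalized) transcript weights.
#' @examples
#' net <- generate_network(n_backbone = 5, genes_per_node = c(3, 3),
#'                         p_neg = 0, seed = 1)
#' length(net$transcript) # 15
#' @export
generate_network <- function(n_backbone = 50, edge_p = 0.08, p_neg = 0.3,
                             genes_per_node = c(15, 25), p_no_genes = 0.1,
                             balanced = FALSE,
                             backbone_model = c("tree", "uniform"),
                             seed = NULL) {
  if (n_backbone < 2) abort("n_backbone must be >= 2")
  backbone_model <- match.arg(backbone_model)
  if (!is.null(seed)) set.seed(seed)
  nodes <- sprintf("bb%03d", seq_len(n_backbone))
  pos_all <- arrayInd(which(upper.tri(matrix(FALSE, n_backbone, n_backbone))),
                      c(n_backbone, n_backbone))

  if (backbone_model == "uniform") {
    n_pairs <- nrow(pos_all)
    C <- round((n_backbone - 1) + edge_p * (n_pairs - (n_backbone - 1)))
    ok <- FALSE
    for (att in 1:1000) {
      pid <- sample.int(n_pairs, C)
      src <- pos_all[pid, 1]; dst <- pos_all[pid, 2]
      g <- igraph::graph_from_data_frame(
        data.frame(src, dst), directed = FALSE,
        vertices = data.frame(name = seq_len(n_backbone)))
      if (igraph::is_connected(g)) { ok <- TRUE; break }
    }
    if (!ok) abort("no connected backbone found in 1000 draws")
  } else {
    # random spanning tree: attach each node to a uniform predecessor
    src <- integer(0); dst <- integer(0)
    for (k in 2:n_backbone) {
      p <- sample.int(k - 1, 1)
      src <- c(src, p); dst <- c(dst, k)
    }
    tree_key <- paste(pmin(src, dst), pmax(src, dst))
    free <- paste(pos_all[, 1], pos_all[, 2])
    pos <- pos_all[!(free %in% tree_key), , drop = FALSE]
    take <- runif(nrow(pos)) < edge_p
    src <- c(src, pos[take, 1]); dst <- c(dst, pos[take, 2])
  }
  ne <- length(src)
  sgn <- ifelse(runif(ne) < p_neg, -1L, 1L)

  if (balanced) {
    # two-color the nodes, then set signs so Gb- has positive edges within
    # groups and negative across: sigma = -1 within, +1 across
    side <- sample(c(-1L, 1L), n_backbone, replace = TRUE)
    sgn <- ifelse(side[src] == side[dst], -1L, 1L)
  }

  bb_edges <- tibble::tibble(
    source = nodes[src], target = nodes[dst], sign = sgn, weight = 1,
    layer_target = "backbone"
  )

  n_skip <- min(floor(p_no_genes * n_backbone), n_backbone - 1)
  skip <- if (n_skip > 0) sample.int(n_backbone, n_skip) else integer(0)
  counts <- integer(n_backbone)
  with_genes <- setdiff(seq_len(n_backbone), skip)
  gpn_range <- seq(genes_per_node[1], genes_per_node[2])
  counts[with_genes] <- if (length(gpn_range) == 1) {
    rep(gpn_range, length(with_genes)) # sample() would misread a scalar
  } else {
    sample(gpn_range, length(with_genes), replace = TRUE)
  }
  gene_sign <- function(n) ifelse(runif(n) < p_neg, -1L, 1L)
  tr_edges <- purrr::map_dfr(which(counts > 0), function(i) {
    tibble::tibble(
      source = nodes[i],
      target = sprintf("g_%s_%03d", nodes[i], seq_len(counts[i])),
      sign = gene_sign(counts[i]), weight = 1, layer_target = "transcript"
    )
  })

  two_layer_network(dplyr::bind_rows(bb_edges, tr_edges))
}

#' Simulate gene fold-changes from planted backbone activity
#'
#' Implements the backward assumption generatively: each transcript gene's
#' expected log2 fold-change is the sign-weighted mean of its regulators'
#' planted activities,
#' \deqn{E[\beta_g] = \frac{1}{|R(g)|}\sum_{x \in R(g)} \sigma(x \to g) f^*(x),}
#' with independent Gaussian noise of standard deviation `noise_sd` on top.
#' The returned `variance` column is `noise_sd^2` (homoscedastic by
#' default, matching the assumption under which the score's confidence
#' interval is derived); `heteroscedastic = TRUE` scales each gene's
#' variance by an independent chi-square-like factor instead.
#'
#' @param net A [two_layer_network()].
#' @param f_star Named numeric vector of planted backbone values covering
#'   every backbone node.
#' @param noise_sd Noise standard deviation (default 0.1).
#' @param seed Optional integer seed.
#' @param heteroscedastic If `TRUE`, per-gene noise variances vary.
#' @return A tibble `gene`, `log2fc`, `variance` covering the transcript
#'   layer.
#' @export
simulate_fold_changes <- function(net, f_star, noise_sd = 0.1, seed = NULL,
                                  heteroscedastic = FALSE) {
  stopifnot(inherits(net, "two_layer_network"))
  miss <- setdiff(net$backbone, names(f_star))
  if (length(miss) > 0) {
    abort(paste0("f_star missing backbone node(s): ",
                 paste(head(miss, 5), collapse = ", ")))
  }
  if (!is.null(seed)) set.seed(seed)
  et <- transcript_edges(net)
  mu_by_gene <- tapply(et$sign * f_star[et$source], et$target, mean)
  mu <- setNames(rep(0, length(net$transcript)), net$transcript)
  mu[names(mu_by_gene)] <- mu_by_gene
  v <- rep(noise_sd^2, length(mu))
  if (heteroscedastic) {
    v <- v * stats::rchisq(length(mu), df = 4) / 4
  }
  tibble::tibble(
    gene = net$transcript,
    log2fc = as.numeric(mu) + rnorm(length(mu), sd = sqrt(v)),
    variance = v
  )
}

#' Simulate a two-class expression cohort
#'
#' Control samples have mean zero on every gene; treated samples have the
#' planted per-gene means of [simulate_fold_changes()]; i.i.d. Gaussian
#' noise per sample and gene. The treated-minus-control difference of group
#' means converges to the planted gene means.
#'
#' @inheritParams simulate_fold_changes
#' @param n_per_class Samples per class (>= 2).
#' @return List with `x` (genes x samples matrix, named dimensions) and
#'   `labels` (tibble `sample`, `class` with classes `control`/`treated`).
#' @export
simulate_cohort <- function(net, f_star, noise_sd = 0.1, n_per_class = 10,
                            seed = NULL) {
  if (n_per_class < 2) abort("n_per_class must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  mu <- simulate_fold_changes(net, f_star, noise_sd = 0)$log2fc
  ng <- length(net$transcript)
  n <- 2 * n_per_class
  x <- matrix(rnorm(ng * n, sd = noise_sd), ng, n)
  x[, seq(n_per_class + 1, n)] <- x[, seq(n_per_class + 1, n)] + mu
  samples <- c(sprintf("ctrl_%02d", seq_len(n_per_class)),
               sprintf("trt_%02d", seq_len(n_per_class)))
  dimnames(x) <- list(net$transcript, samples)
  list(x = x,
       labels = tibble::tibble(
         sample = samples,
         class = rep(c("control", "treated"), each = n_per_class)))
}

#' Generate a complete synthetic study with known truth
#'
#' Bundles a random network, a planted backbone profile, simulated
#' fold-changes and (optionally) a two-class cohort.
#'
#' By default (`consistent = TRUE`) the planted truth is constructed to be
#' exactly recoverable at zero noise: backbone node polarities
#' \eqn{s(x) \in \{\pm 1\}} are drawn first (negative with probability
#' `p_neg`), backbone edge signs are set to \eqn{\sigma(x,y) = s(x)s(y)},
#' and the planted profile is \eqn{f^* = c\,s} with `c = effect`. Such an
#' \eqn{f^*} satisfies every signed backbone relation simultaneously, so it
#' is a stationary point of the smoothing objective and the boundary-value
#' fit returns it exactly when the gene data are noiseless. With
#' `consistent = FALSE` the signs are i.i.d. and \eqn{f^* \sim N(0, c^2)}
#' per node -- a rougher truth the fit can only approximate, useful for
#' calibration and power studies.
#'
#' @inheritParams generate_network
#' @param effect Effect scale c (magnitude of planted backbone values).
#' @param noise_sd Gene-level noise standard deviation.
#' @param consistent Plant a sign-consistent (exactly recoverable) truth?
#' @param cohort If `TRUE`, also simulate a two-class cohort.
#' @param n_per_class Samples per class for the cohort.
#' @param seed Integer seed; the whole study is reproducible from it.
#' @return An `npa_study`: list with `network`, `f_star`, `expression`,
#'   optionally `cohort`, and `params`.
#' @examples
#' study <- simulate_study(n_backbone = 6, genes_per_node = c(3, 5), seed = 1)
#' study$network
#' @export
simulate_study <- function(n_backbone = 50, edge_p = 0.08, p_neg = 0.3,
                           genes_per_node = c(15, 25), p_no_genes = 0.1,
                           effect = 1, noise_sd = 0.1, consistent = TRUE,
                           balanced = FALSE, cohort = FALSE, n_per_class = 10,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  net <- generate_network(n_backbone, edge_p, p_neg, genes_per_node,
                          p_no_genes, balanced = balanced)
  if (consistent && !balanced) {
    side <- sample(c(-1, 1), n_backbone, replace = TRUE,
                   prob = c(p_neg, 1 - p_neg))
    names(side) <- net$backbone
    edges <- net$edges
    is_bb <- edges$layer_target == "backbone"
    edges$sign[is_bb] <- as.integer(side[edges$source[is_bb]] *
                                      side[edges$target[is_bb]])
    net <- two_layer_network(edges, backbone = net$backbone,
                             transcript = net$transcript)
    f_star <- effect * side
  } else {
    f_star <- setNames(rnorm(n_backbone, sd = effect), net$backbone)
  }
  expression <- simulate_fold_changes(net, f_star, noise_sd)
  out <- list(network = net, f_star = f_star, expression = expression,
              params = list(n_backbone = n_backbone, edge_p = edge_p,
                            p_neg = p_neg, genes_per_node = genes_per_node,
                            p_no_genes = p_no_genes, effect = effect,
                            noise_sd = noise_sd, consistent = consistent,
                            balanced = balanced, seed = seed))
  if (cohort) {
    out$cohort <- simulate_cohort(net, f_star, noise_sd, n_per_class)
  }
  structure(out, class = "npa_study")
}

#' @export
print.npa_study <- function(x, ...) {
  cat("<npa_study> backbone", length(x$network$backbone), "nodes /",
      length(x$network$transcript), "genes; effect",
      x$params$effect, "noise_sd", x$params$noise_sd, "\n")
  invisible(x)
}
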