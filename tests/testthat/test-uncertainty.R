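toy_sys <- function() build_laplacians(normalize_downstream_weights(toy_network()))

test_that("backbone covariance matches the hand product and the MC oracle", {
  sys <- toy_sys()
  expr <- tibble::tibble(gene = c("g1", "g2"), log2fc = c(1, 1), variance = 1)
  prof <- backbone_covariance(sys, expr)
  expect_equal(unname(prof$covariance), matrix(c(5, 4, 4, 5), 2) / 9)
  expect_equal(unname(prof$value), c(1, 1))

  # zero variance: zero covariance
  expr0 <- dplyr::mutate(expr, variance = 0)
  expect_equal(unname(backbone_covariance(sys, expr0)$covariance),
               matrix(0, 2, 2))

  # Monte-Carlo cross-check: empirical covariance of f over resampled beta
  set.seed(410)
  n_mc <- 100000
  Bmat <- matrix(rnorm(2 * n_mc, mean = 1, sd = 1), 2, n_mc)
  M <- matrix(c(2, 1, 1, 2), 2) / 3
  Fmat <- M %*% Bmat
  emp <- stats::cov(t(Fmat))
  se <- sqrt(2 / n_mc) # rough SE of a covariance entry at unit scale
  expect_true(all(abs(emp - prof$covariance) < 3 * max(se, 0.02)))

  expect_error(
    backbone_covariance(sys, tibble::tibble(gene = c("g1", "g2"), log2fc = 1)),
    "variance")
})

test_that("score variance: scalar closed form and zero-variance case", {
  # 1-node backbone is impossible (C >= 1 needs 2 nodes); check the scalar
  # algebra through a 2-node system whose profile varies in one coordinate
  sys <- toy_sys()
  expr0 <- tibble::tibble(gene = c("g1", "g2"), log2fc = c(1, 2), variance = 0)
  prof0 <- backbone_covariance(sys, expr0)
  expect_equal(score_variance(sys, prof0), 0)

  # hand value on the toy system: Q = [[1,1],[1,1]], mu = (1,1),
  # Sigma2 = (1/9)[[5,4],[4,5]], C = 1. QSigma = [[1,1],[1,1]],
  # tr(QSQS) = 4, mu' QSQ mu = 8, so var = 2*4 + 4*8 = 40.
  expr1 <- tibble::tibble(gene = c("g1", "g2"), log2fc = c(1, 1), variance = 1)
  prof1 <- backbone_covariance(sys, expr1)
  expect_equal(score_variance(sys, prof1), 40, tolerance = 1e-10)

  expect_error(score_variance(sys, infer_backbone_values(
    sys, tibble::tibble(gene = c("g1", "g2"), log2fc = 1))), "covariance")
})

test_that("score variance matches Monte-Carlo under Gaussian resampling", {
  set.seed(411)
  for (i in 1:6) {
    net <- normalize_downstream_weights(random_test_network(n_backbone = sample(3:6, 1)))
    sys <- build_laplacians(net)
    expr <- random_expression(net)
    prof <- backbone_covariance(sys, expr)
    v_formula <- score_variance(sys, prof)

    n_mc <- 100000
    R <- chol(prof$covariance + 1e-12 * diag(nrow(prof$covariance)))
    H <- prof$value + t(R) %*% matrix(rnorm(length(prof$value) * n_mc),
                                      ncol = n_mc)
    scores <- colSums(H * (sys$Q %*% H)) / sys$C
    v_emp <- var(scores)
    # SE of a sample variance: var * sqrt(2/(n-1)) under near-normality;
    # quadratic forms have excess kurtosis, allow the kurtosis-based SE
    m4 <- mean((scores - mean(scores))^4)
    se <- sqrt((m4 - v_emp^2) / n_mc)
    expect_lt(abs(v_formula - v_emp), 3 * se + 1e-12)
  }
})

test_that("confidence intervals follow the normal quantile and cover the truth", {
  expect_equal(unname(confidence_interval(4, 0)), c(4, 4))
  ci <- confidence_interval(4, 1, level = 0.95)
  expect_equal(unname(ci), c(4 - 1.959964, 4 + 1.959964), tolerance = 1e-6)
  expect_error(confidence_interval(4, -1), ">= 0")
  expect_error(confidence_interval(4, 1, level = 1.2), "level")

  # coverage: resample gene data around a fixed truth, nominal 95%
  set.seed(412)
  net <- normalize_downstream_weights(
    generate_network(n_backbone = 6, edge_p = 0.3, p_neg = 0.3,
                     genes_per_node = c(4, 6), p_no_genes = 0))
  sys <- build_laplacians(net)
  beta0 <- rnorm(length(net$transcript), sd = 1)
  s <- 0.05
  f0 <- -solve(sys$L3, as.numeric(sys$L2 %*% beta0))
  true_score <- as.numeric(crossprod(f0, sys$Q %*% f0)) / sys$C
  n_rep <- 1000
  covered <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    expr <- tibble::tibble(gene = net$transcript,
                           log2fc = beta0 + rnorm(length(beta0), sd = s),
                           variance = s^2)
    prof <- backbone_covariance(sys, expr)
    sc <- topo_npa_score(sys, prof)
    ci_r <- confidence_interval(sc, score_variance(sys, prof))
    covered[r] <- ci_r[["lower"]] <= true_score && true_score <= ci_r[["upper"]]
  }
  # binomial 99.7% band around 0.95 at n = 1000 is ~ +/- 0.021
  expect_gt(mean(covered), 0.95 - 0.03)
  expect_lt(mean(covered), 0.95 + 0.03)
})

test_that("O-statistic: invariance, determinism, add-one p-values", {
  sys <- toy_sys()
  expr_const <- tibble::tibble(gene = c("g1", "g2"), log2fc = 1)
  o <- o_statistic(sys, expr_const, B = 50, seed = 1)
  expect_equal(o$pvalue, 1) # constant beta: every permutation identical
  expect_true(all(o$null_scores == o$observed_score))

  net <- normalize_downstream_weights(random_test_network(n_backbone = 5))
  sys2 <- build_laplacians(net)
  expr <- random_expression(net)
  o1 <- o_statistic(sys2, expr, B = 99, seed = 7)
  o2 <- o_statistic(sys2, expr, B = 99, seed = 7)
  expect_identical(o1$null_scores, o2$null_scores)
  expect_equal(o1$observed_score, topo_npa_score(sys2, infer_backbone_values(sys2, expr)))
  expect_gte(o1$pvalue, 1 / 100)
  expect_lte(o1$pvalue, 1)
  expect_equal(o1$pvalue, (1 + sum(o1$null_scores >= o1$observed_score)) / 100)
})

test_that("K-statistic: degenerate single wiring gives p = 1; seeds reproduce", {
  net <- normalize_downstream_weights(toy_network())
  expr <- tibble::tibble(gene = c("g1", "g2"), log2fc = c(1, -0.5))
  expect_warning(k <- k_statistic(net, expr, B = 30, seed = 3),
                 "single edge")
  expect_equal(k$pvalue, 1)
  expect_true(all(abs(k$null_scores - k$observed_score) < 1e-12))

  set.seed(413)
  net2 <- normalize_downstream_weights(
    generate_network(n_backbone = 6, edge_p = 0.3, genes_per_node = c(2, 3)))
  expr2 <- random_expression(net2)
  k1 <- k_statistic(net2, expr2, B = 40, seed = 11)
  k2 <- k_statistic(net2, expr2, B = 40, seed = 11)
  expect_identical(k1$null_scores, k2$null_scores)
  expect_gte(k1$pvalue, 1 / 41)
  # observed score untouched by resampling
  sys2 <- build_laplacians(net2)
  expect_equal(k1$observed_score,
               topo_npa_score(sys2, infer_backbone_values(sys2, expr2)))
})

test_that("degree-preserving rewiring keeps the degree sequence", {
  set.seed(414)
  net <- normalize_downstream_weights(
    generate_network(n_backbone = 8, edge_p = 0.4, genes_per_node = c(2, 3)))
  expr <- random_expression(net)
  k <- k_statistic(net, expr, B = 20, seed = 5, degree_preserving = TRUE)
  expect_length(k$null_scores, 20)
  expect_gte(k$pvalue, 1 / 21)
})

test_that("planted signal is detected; scrambling destroys O-significance", {
  set.seed(415)
  detected_o <- detected_k <- scrambled_o <- numeric(0)
  for (r in 1:10) {
    study <- simulate_study(n_backbone = 10, edge_p = 0.3, p_neg = 0.3,
                            genes_per_node = c(8, 12), p_no_genes = 0,
                            effect = 2, noise_sd = 0.1)
    net <- normalize_downstream_weights(study$network)
    sys <- build_laplacians(net)
    o <- o_statistic(sys, study$expression, B = 100)
    k <- k_statistic(net, study$expression, B = 100)
    detected_o <- c(detected_o, o$pvalue)
    detected_k <- c(detected_k, k$pvalue)
    scr <- dplyr::mutate(study$expression, log2fc = sample(.data$log2fc))
    scrambled_o <- c(scrambled_o, o_statistic(sys, scr, B = 100)$pvalue)
  }
  expect_gte(mean(detected_o <= 0.05), 0.9)
  expect_gte(mean(detected_k <= 0.05), 0.9)
  expect_gt(mean(scrambled_o > 0.05), 0.7)
})
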