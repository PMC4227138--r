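toy_sys <- function() build_laplacians(normalize_downstream_weights(toy_network()))

test_that("backbone inference reproduces hand solves on the toy system", {
  sys <- toy_sys()
  f1 <- infer_backbone_values(sys, tibble::tibble(gene = c("g1", "g2"),
                                                  log2fc = c(1, 1)))
  expect_equal(unname(f1$value), c(1, 1))

  f2 <- infer_backbone_values(sys, tibble::tibble(gene = c("g1", "g2"),
                                                  log2fc = c(2, 0)))
  expect_equal(unname(f2$value), c(4 / 3, 2 / 3))

  f0 <- infer_backbone_values(sys, tibble::tibble(gene = c("g1", "g2"),
                                                  log2fc = c(0, 0)))
  expect_equal(unname(f0$value), c(0, 0))
})

test_that("closed form matches the constrained-QP oracle on random networks", {
  set.seed(404)
  for (i in 1:100) {
    net <- normalize_downstream_weights(
      random_test_network(n_backbone = sample(3:10, 1)))
    sys <- build_laplacians(net)
    expr <- random_expression(net)
    f <- infer_backbone_values(sys, expr)$value
    beta <- setNames(expr$log2fc, expr$gene)
    f_qp <- qp_oracle_backbone(net, beta)
    expect_equal(unname(f), unname(f_qp[names(f)]), tolerance = 1e-6)
  }
})

test_that("missing transcript genes are reported by id", {
  sys <- toy_sys()
  expect_error(
    infer_backbone_values(sys, tibble::tibble(gene = "g1", log2fc = 1)),
    "g2")
})

test_that("score equals the hand value and the naive edge sum", {
  sys <- toy_sys()
  expect_equal(topo_npa_score(sys, c(1, 1)), 4)
  expect_equal(topo_npa_score(sys, c(0, 0)), 0)

  set.seed(405)
  for (i in 1:30) {
    net <- normalize_downstream_weights(random_test_network())
    sys_i <- build_laplacians(net)
    f <- setNames(rnorm(length(net$backbone)), net$backbone)
    s <- topo_npa_score(sys_i, f)
    expect_gte(s, 0)
    expect_equal(s, unname(naive_score(net, f)), tolerance = 1e-10)
  }
})

test_that("homogeneity: score scales quadratically, f linearly in beta", {
  set.seed(406)
  net <- normalize_downstream_weights(random_test_network(n_backbone = 6))
  sys <- build_laplacians(net)
  expr <- random_expression(net)
  f1 <- infer_backbone_values(sys, expr)$value
  s1 <- topo_npa_score(sys, f1)
  for (c in c(0.5, 2, 4)) {
    expr_c <- dplyr::mutate(expr, log2fc = .data$log2fc * c)
    fc <- infer_backbone_values(sys, expr_c)$value
    expect_equal(unname(fc), unname(c * f1), tolerance = 1e-12)
    expect_equal(topo_npa_score(sys, fc), c^2 * s1, tolerance = 1e-10)
  }
})

test_that("spectral envelope brackets the score; toy attains the upper bound", {
  sys <- toy_sys()
  b <- score_bounds(sys, c(1, 1))
  expect_equal(unname(b), c(0, 4))
  expect_equal(topo_npa_score(sys, c(1, 1)), b[["upper"]]) # top eigenvector

  expect_equal(unname(score_bounds(sys, c(0, 0))), c(0, 0))

  set.seed(407)
  for (i in 1:100) {
    net <- normalize_downstream_weights(random_test_network())
    sys_i <- build_laplacians(net)
    for (r in 1:5) {
      f <- rnorm(length(net$backbone))
      s <- topo_npa_score(sys_i, f)
      b <- score_bounds(sys_i, f)
      expect_gte(s, b[["lower"]] - 1e-8 * max(1, s))
      expect_lte(s, b[["upper"]] + 1e-8 * max(1, s))
    }
  }
})

test_that("balanced sign-flipped backbone with piecewise-constant f scores zero", {
  set.seed(408)
  for (i in 1:10) {
    net <- generate_network(n_backbone = sample(4:10, 1), edge_p = 0.4,
                            genes_per_node = c(1, 2), balanced = TRUE)
    expect_true(is_balanced(net))
    net <- normalize_downstream_weights(net)
    sys <- build_laplacians(net)
    # the kernel of Q is spanned by the +/-1 indicator of the partition;
    # recover it from the zero eigenvector and plant f = +/-1 accordingly
    edec <- eigen(sys$Q, symmetric = TRUE)
    v0 <- edec$vectors[, which.min(edec$values)]
    f <- ifelse(v0 >= 0, 1, -1)
    expect_equal(topo_npa_score(sys, f), 0, tolerance = 1e-12)
    expect_equal(min(sys$Q_eigenvalues), 0, tolerance = 1e-10)
  }
})

test_that("contributions sum to 100, rank deterministically, and flag leaders", {
  sys <- toy_sys()
  tab <- node_contributions(sys, c(1, 1))
  expect_equal(sum(tab$contribution), 100, tolerance = 1e-6)
  expect_equal(sort(tab$contribution), c(50, 50))
  expect_true(all(tab$leading)) # 50 < 80 <= 100: both leading
  expect_equal(tab$direction, c("+", "+"))

  set.seed(409)
  for (i in 1:20) {
    net <- normalize_downstream_weights(random_test_network())
    sys_i <- build_laplacians(net)
    f <- rnorm(length(net$backbone))
    tab_i <- node_contributions(sys_i, f)
    expect_equal(sum(tab_i$contribution), 100, tolerance = 1e-6)
    expect_equal(tab_i$rank, seq_len(nrow(tab_i)))
    expect_true(!is.unsorted(rev(tab_i$contribution), strictly = FALSE))
  }

  expect_error(node_contributions(sys, c(0, 0)), "no perturbation")
})

test_that("a node with f = 0 contributes nothing", {
  net <- two_layer_network(tibble::tibble(
    source = c("a", "b", "a", "b", "c"),
    target = c("b", "c", "g1", "g2", "g3"),
    sign = c(1, 1, 1, 1, 1),
    layer_target = c("backbone", "backbone", rep("transcript", 3))))
  sys <- build_laplacians(normalize_downstream_weights(net))
  tab <- node_contributions(sys, setNames(c(1, 0, -1), c("a", "b", "c")))
  expect_equal(tab$contribution[tab$node == "b"], 0)
  expect_equal(tab$direction[tab$node == "b"], "0")
})

test_that("leading-node threshold logic is the minimal qualifying prefix", {
  tab <- tibble::tibble(node = c("x", "y", "z"),
                        contribution = c(85, 10, 5), rank = 1:3)
  out <- leading_nodes(tab)
  expect_equal(out$leading, c(TRUE, FALSE, FALSE))

  out2 <- leading_nodes(tibble::tibble(node = c("a", "b"),
                                       contribution = c(50, 50), rank = 1:2))
  expect_true(all(out2$leading))

  out3 <- leading_nodes(tab, cumulative_threshold = 1)
  expect_true(all(out3$leading))

  expect_error(leading_nodes(tab, cumulative_threshold = 0), "0, 1")
  expect_error(leading_nodes(tab, cumulative_threshold = 1.2), "0, 1")
})
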