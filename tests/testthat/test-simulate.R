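test_that("generator echoes its parameters and is seed-reproducible", {
  net <- generate_network(n_backbone = 5, genes_per_node = c(3, 3),
                          p_neg = 0, p_no_genes = 0, seed = 1)
  expect_length(net$backbone, 5)
  expect_length(net$transcript, 15)
  expect_true(all(net$edges$sign == 1))
  expect_equal(nrow(validate_network(net)), 0)

  net2 <- generate_network(n_backbone = 5, genes_per_node = c(3, 3),
                           p_neg = 0, p_no_genes = 0, seed = 1)
  expect_identical(net$edges, net2$edges)

  net3 <- generate_network(n_backbone = 5, genes_per_node = c(3, 3),
                           p_neg = 0, p_no_genes = 0, seed = 2)
  expect_false(identical(net$edges, net3$edges))

  expect_error(generate_network(n_backbone = 1), ">= 2")
})

test_that("balanced construction yields a balanced sign-flipped backbone", {
  for (s in 1:10) {
    net <- generate_network(n_backbone = 7, edge_p = 0.5, p_neg = 0.5,
                            genes_per_node = c(1, 2), balanced = TRUE,
                            seed = s)
    expect_true(is_balanced(net))
  }
})

test_that("generated backbones are always connected", {
  set.seed(419)
  for (i in 1:20) {
    net <- generate_network(n_backbone = sample(2:30, 1), edge_p = 0.05,
                            genes_per_node = c(1, 3))
    expect_equal(backbone_components_count(net), 1)
  }
})


test_that("fold-change simulation implements the regulator-mean model", {
  net <- generate_network(n_backbone = 5, genes_per_node = c(2, 4),
                          p_no_genes = 0, seed = 3)
  f_star <- setNames(rnorm(5), net$backbone)
  de <- simulate_fold_changes(net, f_star, noise_sd = 0, seed = 4)
  et <- net$edges[net$edges$layer_target == "transcript", ]
  for (k in sample(nrow(et), 5)) {
    expect_equal(de$log2fc[de$gene == et$target[k]],
                 unname(et$sign[k] * f_star[et$source[k]]))
  }
  expect_true(all(de$variance == 0))
  expect_error(simulate_fold_changes(net, f_star[-1]), "missing backbone")
})

test_that("consistent studies recover the planted truth exactly at zero noise", {
  for (s in 1:5) {
    study <- simulate_study(n_backbone = 8, edge_p = 0.4, p_neg = 0.3,
                            genes_per_node = c(2, 4), p_no_genes = 0.2,
                            effect = 1.5, noise_sd = 0, seed = s)
    net <- normalize_downstream_weights(study$network)
    sys <- build_laplacians(net)
    f_hat <- infer_backbone_values(sys, study$expression)$value
    expect_equal(unname(f_hat[names(study$f_star)]),
                 unname(study$f_star), tolerance = 1e-10)
  }
})

test_that("cohort group-mean difference recovers the planted gene means", {
  net <- generate_network(n_backbone = 6, genes_per_node = c(4, 6),
                          p_no_genes = 0, seed = 6)
  f_star <- setNames(rnorm(6), net$backbone)
  noise_sd <- 0.1; n <- 50
  cht <- simulate_cohort(net, f_star, noise_sd = noise_sd, n_per_class = n,
                         seed = 7)
  mu <- simulate_fold_changes(net, f_star, noise_sd = 0)$log2fc
  lab <- cht$labels
  d <- rowMeans(cht$x[, lab$class == "treated"]) -
    rowMeans(cht$x[, lab$class == "control"])
  se <- noise_sd * sqrt(2 / n)
  expect_true(all(abs(d - mu) < 4.5 * se)) # ~300 genes: 4.5 SE keeps the
  # family-wise false-alarm chance negligible

  # zero noise: all treated columns identical
  cht0 <- simulate_cohort(net, f_star, noise_sd = 0, n_per_class = 3, seed = 8)
  trt <- cht0$x[, cht0$labels$class == "treated"]
  expect_true(all(trt == trt[, 1]))
  expect_true(all(cht0$x[, cht0$labels$class == "control"] == 0))

  expect_error(simulate_cohort(net, f_star, n_per_class = 1), ">= 2")
})

test_that("noisy planted truth is recovered with high fidelity", {
  cors <- vapply(1:5, function(s) {
    study <- simulate_study(n_backbone = 20, edge_p = 0.15, p_neg = 0.3,
                            genes_per_node = c(10, 20), p_no_genes = 0.1,
                            effect = 1, noise_sd = 0.1, seed = 100 + s)
    net <- normalize_downstream_weights(study$network)
    sys <- build_laplacians(net)
    f_hat <- infer_backbone_values(sys, study$expression)$value
    cor(unname(f_hat[names(study$f_star)]), unname(study$f_star))
  }, numeric(1))
  expect_true(all(cors > 0.9))
})

test_that("dose response: score grows with the planted effect scale", {
  set.seed(420)
  mean_scores <- vapply(c(0.5, 1, 2, 4), function(effect) {
    mean(vapply(1:5, function(r) {
      study <- simulate_study(n_backbone = 10, edge_p = 0.3, p_neg = 0.3,
                              genes_per_node = c(5, 8), p_no_genes = 0,
                              effect = effect, noise_sd = 0.1)
      net <- normalize_downstream_weights(study$network)
      sys <- build_laplacians(net)
      topo_npa_score(sys, infer_backbone_values(sys, study$expression))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_scores) > 0))
})

test_that("synthetic objects round-trip through the writers bit-exactly", {
  dir <- withr::local_tempdir()
  study <- simulate_study(n_backbone = 5, genes_per_node = c(2, 3),
                          p_no_genes = 0, cohort = TRUE, n_per_class = 3,
                          seed = 9)
  tsv <- file.path(dir, "net.tsv"); jsn <- file.path(dir, "net.json")
  write_network(study$network, tsv)
  write_network(study$network, jsn, format = "network_json")
  for (p in c(tsv, jsn)) {
    back <- read_network(p)
    expect_identical(back$backbone, study$network$backbone)
    expect_identical(back$transcript, study$network$transcript)
    expect_equal(back$edges, study$network$edges)
  }
  mp <- file.path(dir, "cohort.tsv")
  write_expression_matrix(study$cohort$x, mp)
  expect_equal(read_expression_matrix(mp), study$cohort$x)
})
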