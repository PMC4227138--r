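#' Assemble a reproducible run configuration
#'
#' Collects every knob of a scoring or signature run into one serializable
#' list; the configuration is echoed as `config.json` into each run's
#' output directory so a run can be reproduced from its outputs alone.
#'
#' @param network Path to a network file (TSV or JSON dialect).
#' @param expression Path to an expression table or matrix.
#' @param labels Optional path to a `sample class` TSV.
#' @param out Output directory.
#' @param B Permutations per companion statistic.
#' @param level Confidence level.
#' @param leading_threshold Leading-node cumulative fraction.
#' @param seed Integer seed.
#' @param o_pool,k_degree_preserving,largest_component Pipeline flags, see
#'   [npa()].
#' @return A named list of class `npa_config`.
#' @export
run_config <- function(network = NULL, expression = NULL, labels = NULL,
                       out = ".", B = 500, level = 0.95,
                       leading_threshold = 0.8, seed = NULL,
                       o_pool = "network", k_degree_preserving = FALSE,
                       largest_component = FALSE) {
  structure(
    list(network = network, expression = expression, labels = labels,
         out = out, B = B, level = level,
         leading_threshold = leading_threshold, seed = seed,
         o_pool = o_pool, k_degree_preserving = k_degree_preserving,
         largest_component = largest_component,
         package_version = as.character(utils::packageVersion("toponpa"))),
    class = "npa_config"
  )
}

echo_config <- function(config, dir) {
  jsonlite::write_json(unclass(config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
}

ensure_out_dir <- function(dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(paste0("cannot create output directory: ", dir))
  }
  dir
}

#' Run the scoring pipeline from files to files
#'
#' Reads the network and expression table, runs [npa()], and writes
#' `npa.json` (score, CI, p-values, null distributions), `contributions.tsv`
#' and the echoed `config.json` into the output directory.
#'
#' @param config An [run_config()] list.
#' @return The [npa()] fit, invisibly.
#' @export
run_score <- function(config) {
  stopifnot(inherits(config, "npa_config"))
  message("reading network: ", config$network)
  net <- read_network(config$network)
  message("reading expression: ", config$expression)
  expr <- read_expression(config$expression)
  message("scoring (B = ", config$B, ")")
  fit <- npa(expr, net, B = config$B, level = config$level,
             leading_threshold = config$leading_threshold,
             seed = config$seed, o_pool = config$o_pool,
             k_degree_preserving = config$k_degree_preserving,
             largest_component = config$largest_component)
  dir <- ensure_out_dir(config$out)
  jsonlite::write_json(npa_as_list(fit), file.path(dir, "npa.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  readr::write_tsv(tidy(fit), file.path(dir, "contributions.tsv"))
  echo_config(config, dir)
  message("score = ", format(fit$score, digits = 6),
          "  [", significance_label(fit), "]")
  invisible(fit)
}

npa_as_list <- function(fit) {
  perm_list <- function(p) {
    if (is.null(p)) return(NULL)
    list(statistic = p$statistic, observed_score = p$observed_score,
         pvalue = p$pvalue, B = p$B, seed = p$seed, redraws = p$redraws,
         null_scores = p$null_scores)
  }
  list(
    score = fit$score,
    ci = as.list(fit$ci), variance = fit$variance, level = fit$level,
    bounds = as.list(fit$bounds),
    o = perm_list(fit$o), k = perm_list(fit$k),
    backbone_values = as.list(fit$profile$value),
    contributions = fit$contributions,
    leading_threshold = fit$leading_threshold,
    n_backbone = length(fit$system$backbone),
    n_genes = length(fit$system$transcript),
    n_backbone_edges = fit$system$C
  )
}

#' Run the signature pipeline from files to files
#'
#' Reads a genes x samples matrix, centers it, maps every sample to
#' backbone values, and writes `backbone_values.tsv` (backbone nodes as
#' rows) plus a PCA summary and the echoed configuration.
#'
#' @param config An [run_config()] list.
#' @return The `sample_backbone_matrix`, invisibly.
#' @export
run_signature <- function(config) {
  stopifnot(inherits(config, "npa_config"))
  net <- read_network(config$network)
  x <- read_expression_matrix(config$expression)
  labels <- NULL
  if (!is.null(config$labels)) {
    labels <- readr::read_tsv(config$labels, show_col_types = FALSE)
    stopifnot(all(c("sample", "class") %in% names(labels)))
    unknown <- setdiff(labels$sample, colnames(x))
    if (length(unknown) > 0) {
      abort(paste0("label file names unknown sample(s): ",
                   paste(unknown, collapse = ", ")))
    }
  }
  net <- normalize_downstream_weights(net, expression_genes = rownames(x))
  sys <- build_laplacians(net)
  xc <- center_expression(x)
  sbm <- map_samples_to_backbone(sys, xc)
  dir <- ensure_out_dir(config$out)
  write_expression_matrix(sbm$values, file.path(dir, "backbone_values.tsv"))
  pc <- stats::prcomp(t(sbm$values), center = TRUE)
  pvar <- pc$sdev^2 / sum(pc$sdev^2)
  jsonlite::write_json(
    list(n_backbone = length(sbm$backbone), n_samples = length(sbm$samples),
         pc_variance_fraction = pvar[seq_len(min(5, length(pvar)))]),
    file.path(dir, "pca_summary.json"), auto_unbox = TRUE, digits = NA)
  echo_config(config, dir)
  message("mapped ", length(sbm$samples), " samples onto ",
          length(sbm$backbone), " backbone nodes")
  invisible(sbm)
}

#' Materialize a synthetic study on disk
#'
#' Generates a [simulate_study()] and writes `network.tsv`,
#' `expression.tsv`, `cohort.tsv`, `labels.tsv`, `truth.json` (planted
#' backbone values) and a manifest with the generator parameters. Fully
#' deterministic given the seed.
#'
#' @param config An [run_config()] list; `seed` and `out` are used.
#' @param ... Passed on to [simulate_study()].
#' @return The study, invisibly.
#' @export
run_simulate <- function(config, ...) {
  stopifnot(inherits(config, "npa_config"))
  study <- simulate_study(..., cohort = TRUE, seed = config$seed)
  dir <- ensure_out_dir(config$out)
  write_network(study$network, file.path(dir, "network.tsv"))
  readr::write_tsv(study$expression, file.path(dir, "expression.tsv"))
  write_expression_matrix(study$cohort$x, file.path(dir, "cohort.tsv"))
  readr::write_tsv(study$cohort$labels, file.path(dir, "labels.tsv"))
  jsonlite::write_json(list(f_star = as.list(study$f_star)),
                       file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(study$params, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  echo_config(config, dir)
  invisible(study)
}

#' Validate a network file and report violations
#'
#' @param config An [run_config()] list (`network`, `out`).
#' @return The violation tibble, invisibly; also written as
#'   `validation.json`.
#' @export
run_validate <- function(config) {
  stopifnot(inherits(config, "npa_config"))
  net <- read_network(config$network)
  report <- validate_network(net)
  dir <- ensure_out_dir(config$out)
  jsonlite::write_json(
    list(valid = nrow(report) == 0, violations = report),
    file.path(dir, "validation.json"), auto_unbox = TRUE, digits = NA)
  if (nrow(report) == 0) message("network is valid")
  else message(nrow(report), " violation(s); see validation.json")
  invisible(report)
}
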