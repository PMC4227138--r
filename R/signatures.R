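#' Center an expression matrix gene-wise
#'
#' Subtracts per-gene means so each sample's profile becomes a differential
#' value against the population average -- the single-sample analogue of a
#' fold-change. For external-cohort prediction, supply the training-cohort
#' means as `reference` so the test data are centered without looking at
#' their own labels or distribution (the test rows then generally keep
#' nonzero means).
#'
#' @param x Genes x samples numeric matrix with gene row names, or a data
#'   frame whose first column `gene` holds the ids.
#' @param reference Optional named per-gene means to subtract instead of
#'   the matrix's own row means.
#' @return The centered matrix, with the means used attached as attribute
#'   `"reference"`.
#' @export
center_expression <- function(x, reference = NULL) {
  x <- as_expression_matrix(x)
  if (is.null(reference)) {
    reference <- rowMeans(x)
  } else {
    if (is.null(names(reference)) || !all(rownames(x) %in% names(reference))) {
      miss <- setdiff(rownames(x), names(reference))
      abort(paste0("reference means missing for ", length(miss),
                   " gene(s): ", paste(head(miss, 5), collapse = ", ")))
    }
    reference <- reference[rownames(x)]
  }
  out <- x - reference
  attr(out, "reference") <- reference
  out
}

as_expression_matrix <- function(x) {
  if (is.data.frame(x)) {
    stopifnot("gene" %in% names(x))
    genes <- as.character(x$gene)
    m <- as.matrix(x[setdiff(names(x), "gene")])
    rownames(m) <- genes
    x <- m
  }
  if (!is.matrix(x) || is.null(rownames(x))) {
    abort("expression matrix needs gene row names (or a `gene` column)")
  }
  storage.mode(x) <- "double"
  x
}

#' Map individual samples to backbone values
#'
#' Applies the data-independent linear map \eqn{B = -L_3^{-1} L_2 X_c} to a
#' centered genes x samples matrix, one Cholesky factorization solving all
#' columns at once. Each column of B equals [infer_backbone_values()] run on
#' that sample's centered profile, and by linearity the difference of group
#' means of B equals the backbone values inferred from the group-mean
#' fold-changes -- the coherence property that lets network scoring and
#' per-sample classification features live in the same space.
#'
#' @param sys A [build_laplacians()] system.
#' @param xc Centered matrix from [center_expression()]; rows must cover the
#'   transcript layer of `sys`.
#' @return A `sample_backbone_matrix`: list with `values` (backbone x
#'   samples matrix), `backbone`, `samples`, and `centering_reference`.
#' @export
map_samples_to_backbone <- function(sys, xc) {
  xc_ref <- attr(xc, "reference")
  xc <- as_expression_matrix(xc)
  idx <- match(sys$transcript, rownames(xc))
  if (anyNA(idx)) {
    miss <- sys$transcript[is.na(idx)]
    abort(paste0("centered matrix missing ", length(miss),
                 " transcript gene(s): ",
                 paste(head(miss, 10), collapse = ", ")))
  }
  B <- -solve_L3(sys, as.matrix(sys$L2 %*% xc[idx, , drop = FALSE]))
  dimnames(B) <- list(sys$backbone, colnames(xc))
  structure(
    list(values = B, backbone = sys$backbone, samples = colnames(xc),
         centering_reference = xc_ref),
    class = "sample_backbone_matrix"
  )
}

#' @export
print.sample_backbone_matrix <- function(x, ...) {
  cat("<sample_backbone_matrix> ", length(x$backbone), " backbone nodes x ",
      length(x$samples), " samples\n", sep = "")
  invisible(x)
}
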