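#' Read a two-layer network from disk
#'
#' Two plain-text dialects are supported. `edge_tsv`: a tab-separated table
#' with header `source target sign layer_target [weight]`, sign tokens
#' `+1`/`-1`/`+`/`-`, `layer_target` one of `backbone`/`transcript`, and
#' `#` comment lines. `network_json`: a single document
#' `{"backbone": [...], "transcript": [...], "edges": [{"source", "target",
#' "sign", "weight"}]}`.
#'
#' @param path File path.
#' @param format `"edge_tsv"` (default, inferred from a `.json` extension
#'   otherwise) or `"network_json"`.
#' @return A [two_layer_network()].
#' @export
read_network <- function(path, format = c("auto", "edge_tsv", "network_json")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("network file not found: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE))
      "network_json" else "edge_tsv"
  }
  if (format == "network_json") {
    doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    for (fld in c("backbone", "transcript", "edges")) {
      if (is.null(doc[[fld]])) {
        abort(paste0("network JSON lacks field `", fld, "`"))
      }
    }
    edges <- tibble::as_tibble(doc$edges)
    if (!"weight" %in% names(edges)) edges$weight <- 1
    return(two_layer_network(edges, backbone = doc$backbone,
                             transcript = doc$transcript))
  }
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  raw_line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) < 2) abort("network TSV has no data rows")
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  required <- c("source", "target", "sign", "layer_target")
  if (!all(required %in% header)) {
    abort(paste0("network TSV header must contain: ",
                 paste(required, collapse = ", ")))
  }
  fields <- strsplit(lines[-1], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != length(header))) {
    bad <- raw_line_no[-1][nf != length(header)][1]
    abort(paste0("malformed row at line ", bad, ": expected ",
                 length(header), " fields"))
  }
  tab <- tibble::as_tibble(setNames(
    as.data.frame(do.call(rbind, fields), stringsAsFactors = FALSE), header))
  if ("weight" %in% names(tab)) {
    tab$weight <- suppressWarnings(as.numeric(tab$weight))
    if (anyNA(tab$weight)) abort("non-numeric weight value")
  }
  two_layer_network(tab)
}

#' Write a two-layer network
#'
#' @param net A [two_layer_network()].
#' @param path Output file path.
#' @param format `"edge_tsv"` or `"network_json"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("edge_tsv", "network_json")) {
  format <- match.arg(format)
  if (format == "edge_tsv") {
    readr::write_tsv(net$edges[, c("source", "target", "sign",
                                   "layer_target", "weight")], path)
  } else {
    jsonlite::write_json(
      list(backbone = net$backbone, transcript = net$transcript,
           edges = net$edges[, c("source", "target", "sign", "weight")]),
      path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a differential-expression table
#'
#' Tab-separated with header `gene log2fc [variance]` (e.g. exported from a
#' limma-style fit: coefficient and squared standard error per gene).
#'
#' @param path File path.
#' @return Tibble `gene`, `log2fc`, and `variance` when present.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) abort(paste0("expression file not found: ", path))
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  if (!all(c("gene", "log2fc") %in% names(tab))) {
    abort("expression table must have columns `gene` and `log2fc`")
  }
  tab$gene <- as.character(tab$gene)
  tab
}

#' Read a genes x samples expression matrix
#'
#' Tab-separated; first column `gene`, remaining columns one per sample.
#'
#' @param path File path.
#' @return Numeric matrix with gene row names.
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) abort(paste0("matrix file not found: ", path))
  as_expression_matrix(readr::read_tsv(path, comment = "#",
                                       show_col_types = FALSE))
}

#' Write a genes x samples matrix as TSV
#' @param x Matrix with gene row names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  tab <- tibble::as_tibble(x, rownames = "gene")
  readr::write_tsv(tab, path)
  invisible(path)
}
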