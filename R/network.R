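#' Construct a two-layer causal network
#'
#' A two-layer network couples a signed, directed "backbone" of functional
#' nodes (protein activities, transcription-factor activities, compounds)
#' to a "transcript" layer of measurable genes. Backbone nodes may regulate
#' each other and their downstream genes; transcript nodes are pure sinks
#' and never appear as edge sources.
#'
#' @param edges A data frame with columns `source`, `target`, `sign`
#'   (`+1`/`-1`, or the tokens `"+"`/`"-"`), and optionally `weight`
#'   (strictly positive; default 1) and `layer_target`
#'   (`"backbone"`/`"transcript"`). `layer_target` is required unless the
#'   node sets are given explicitly.
#' @param backbone,transcript Optional character vectors naming the nodes of
#'   each layer explicitly. When omitted, layer membership is taken from the
#'   `layer_target` column: a node is a transcript node if it appears as the
#'   target of an edge flagged `transcript`.
#'
#' @return An object of class `two_layer_network`: a list with elements
#'   `backbone` (ordered node ids), `transcript` (ordered gene ids) and
#'   `edges` (a tibble `source`, `target`, `sign`, `weight`, `layer_target`).
#'   Node order is first-appearance order.
#'
#' @details Structural defects that make downstream matrices meaningless are
#'   rejected here (unknown sign token, duplicate directed edge, transcript
#'   node used as a source, non-positive weight, endpoint not in a declared
#'   layer). Softer requirements -- backbone connectivity, presence of
#'   transcript-layer edges, absence of self-loops -- are reported by
#'   [validate_network()].
#'
#' @examples
#' edges <- tibble::tibble(
#'   source = c("a", "a", "b"),
#'   target = c("b", "g1", "g2"),
#'   sign = c(1, 1, 1),
#'   layer_target = c("backbone", "transcript", "transcript")
#' )
#' net <- two_layer_network(edges)
#' net
#' @export
two_layer_network <- function(edges, backbone = NULL, transcript = NULL) {
  edges <- tibble::as_tibble(edges)
  required <- c("source", "target", "sign")
  missing_cols <- setdiff(required, names(edges))
  if (length(missing_cols) > 0) {
    abort(paste0("edge table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(edges) == 0) abort("edge table is empty")

  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  edges$sign <- parse_sign(edges$sign)
  if (!"weight" %in% names(edges)) edges$weight <- 1
  edges$weight <- as.numeric(edges$weight)
  if (any(!is.finite(edges$weight) | edges$weight <= 0)) {
    abort("all edge weights must be finite and strictly positive")
  }

  dup <- duplicated(paste(edges$source, edges$target, sep = "\r"))
  if (any(dup)) {
    abort(paste0("duplicate edge(s): ",
                 paste(unique(paste0(edges$source[dup], " -> ",
                                     edges$target[dup])), collapse = ", ")))
  }

  if (is.null(backbone) || is.null(transcript)) {
    if (!"layer_target" %in% names(edges)) {
      abort("either supply `backbone` and `transcript`, or a `layer_target` column")
    }
    lt <- as.character(edges$layer_target)
    bad <- setdiff(unique(lt), c("backbone", "transcript"))
    if (length(bad) > 0) {
      abort(paste0("unknown layer_target value(s): ", paste(bad, collapse = ", ")))
    }
    transcript <- unique(edges$target[lt == "transcript"])
    backbone <- unique(c(edges$source, edges$target[lt == "backbone"]))
    backbone <- setdiff(backbone, transcript)
  } else {
    backbone <- as.character(backbone)
    transcript <- as.character(transcript)
  }

  overlap <- intersect(backbone, transcript)
  if (length(overlap) > 0) {
    abort(paste0("node(s) in both layers: ", paste(overlap, collapse = ", ")))
  }
  all_nodes <- c(backbone, transcript)
  undeclared <- setdiff(unique(c(edges$source, edges$target)), all_nodes)
  if (length(undeclared) > 0) {
    abort(paste0("edge references undeclared node(s): ",
                 paste(undeclared, collapse = ", ")))
  }

  from_transcript <- edges$source %in% transcript
  if (any(from_transcript)) {
    abort(paste0("transcript node as source: ",
                 paste(unique(edges$source[from_transcript]), collapse = ", ")))
  }

  edges$layer_target <- ifelse(edges$target %in% transcript,
                               "transcript", "backbone")

  structure(
    list(backbone = backbone, transcript = transcript,
         edges = edges[, c("source", "target", "sign", "weight", "layer_target")]),
    class = "two_layer_network"
  )
}

parse_sign <- function(x) {
  tok <- trimws(as.character(x))
  out <- rep(NA_integer_, length(tok))
  out[tok %in% c("+1", "+", "1")] <- 1L
  out[tok %in% c("-1", "-")] <- -1L
  if (anyNA(out)) {
    bad <- unique(tok[is.na(out)])
    abort(paste0("unknown sign token(s): ", paste(bad, collapse = ", "),
                 " (expected +1, -1, + or -)"))
  }
  out
}

#' @export
print.two_layer_network <- function(x, ...) {
  eb <- backbone_edges(x)
  cat("<two_layer_network>\n")
  cat("  backbone:  ", length(x$backbone), " nodes, ", nrow(eb), " edges (",
      sum(eb$sign < 0), " negative)\n", sep = "")
  cat("  transcript:", length(x$transcript), "genes,",
      sum(x$edges$layer_target == "transcript"), "downstream edges\n")
  invisible(x)
}

backbone_edges <- function(net) {
  dplyr::filter(net$edges, .data$layer_target == "backbone")
}

transcript_edges <- function(net) {
  dplyr::filter(net$edges, .data$layer_target == "transcript")
}

#' Validate a two-layer network
#'
#' Checks the structural requirements that the perturbation machinery relies
#' on and reports violations without mutating the input: disjoint layers,
#' strictly positive weights, no self-loops, an (undirected) connected
#' backbone, at least one backbone-to-transcript edge, and no contradictory
#' reciprocal backbone edges.
#'
#' Connectivity of the undirected backbone, together with at least one
#' downstream transcript edge, is what makes the backbone block of the signed
#' Laplacian irreducibly diagonally dominant and hence invertible.
#'
#' @param net A [two_layer_network()].
#' @return A tibble with columns `check` and `message`, one row per
#'   violation; zero rows when the network is valid.
#' @examples
#' net <- toy_network()
#' validate_network(net) # zero rows
#' @export
validate_network <- function(net) {
  stopifnot(inherits(net, "two_layer_network"))
  violations <- list()
  add <- function(check, message) {
    violations[[length(violations) + 1]] <<- tibble::tibble(
      check = check, message = message)
  }

  loops <- net$edges$source == net$edges$target
  if (any(loops)) {
    add("self_loop", paste0("self-loop on node(s): ",
                            paste(unique(net$edges$source[loops]), collapse = ", ")))
  }

  te <- transcript_edges(net)
  if (nrow(te) == 0) {
    add("no_transcript_edges", "no transcript-layer downstream edges")
  }

  comp <- backbone_components(net)
  if (comp$n_components > 1) {
    add("backbone_disconnected",
        paste0("backbone not connected (", comp$n_components, " components; sizes ",
               paste(comp$sizes, collapse = ", "), ")"))
  }

  eb <- backbone_edges(net)
  eb <- dplyr::filter(eb, .data$source != .data$target)
  if (nrow(eb) > 0) {
    key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
    k <- key(eb$source, eb$target)
    contradicted <- vapply(split(eb$sign, k),
                           function(s) length(unique(s)) > 1, logical(1))
    if (any(contradicted)) {
      pairs <- gsub("\r", " -- ", names(contradicted)[contradicted])
      add("contradictory_reciprocal_edges",
          paste0("reciprocal backbone edges with opposite signs: ",
                 paste(pairs, collapse = ", ")))
    }
  }

  if (length(violations) == 0) {
    tibble::tibble(check = character(), message = character())
  } else {
    dplyr::bind_rows(violations)
  }
}

# Connected components of the undirected backbone subgraph.
backbone_components <- function(net) {
  eb <- backbone_edges(net)
  g <- igraph::graph_from_data_frame(
    eb[, c("source", "target")], directed = FALSE,
    vertices = data.frame(name = net$backbone)
  )
  comp <- igraph::components(g)
  list(n_components = comp$no, sizes = unname(comp$csize),
       membership = comp$membership[net$backbone])
}

#' Restrict a network to its largest backbone component
#'
#' Drops backbone nodes outside the largest connected component of the
#' undirected backbone, together with their edges and exclusive downstream
#' genes, and warns about what was removed. Useful when a curated model
#' arrives fragmented.
#'
#' @param net A [two_layer_network()].
#' @return A [two_layer_network()] with a connected backbone.
#' @export
largest_backbone_component <- function(net) {
  comp <- backbone_components(net)
  if (comp$n_components == 1) return(net)
  keep_id <- which.max(comp$sizes)
  keep <- names(comp$membership)[comp$membership == keep_id]
  dropped <- setdiff(net$backbone, keep)
  warn(paste0("dropping ", length(dropped),
              " backbone node(s) outside the largest component"))
  edges <- dplyr::filter(net$edges, !(.data$source %in% dropped) &
                           !(.data$target %in% dropped))
  transcript <- intersect(net$transcript, unique(edges$target))
  two_layer_network(edges, backbone = keep, transcript = transcript)
}

#' Normalize downstream (transcript-layer) edge weights
#'
#' Gives every backbone node a total transcript out-weight of one: a node
#' with \eqn{n_x} downstream genes gets weight \eqn{1/n_x} on each of those
#' edges. Heavily curated nodes with hundreds of downstream genes would
#' otherwise dominate the fit purely through literature coverage; after
#' normalization all genes of a node share its unit of influence equally and
#' the backbone structure keeps its weight relative to the (much larger)
#' transcript layer. Backbone-to-backbone weights are left untouched.
#'
#' @param net A [two_layer_network()].
#' @param expression_genes Optional character vector of measured gene ids.
#'   When given, transcript nodes not in this set are dropped (with their
#'   edges) before the per-node counts are taken, so weights renormalize to
#'   the measured subset.
#' @return A new [two_layer_network()]; idempotent.
#' @examples
#' net <- toy_network()
#' normalize_downstream_weights(net)
#' @export
normalize_downstream_weights <- function(net, expression_genes = NULL) {
  stopifnot(inherits(net, "two_layer_network"))
  edges <- net$edges
  transcript <- net$transcript
  if (!is.null(expression_genes)) {
    transcript <- intersect(transcript, as.character(expression_genes))
    if (length(transcript) == 0) abort("no measured downstream genes")
    edges <- dplyr::filter(edges, .data$layer_target == "backbone" |
                             .data$target %in% transcript)
  }
  is_tr <- edges$layer_target == "transcript"
  if (any(is_tr)) {
    n_down <- table(edges$source[is_tr])
    edges$weight[is_tr] <- 1 / as.numeric(n_down[edges$source[is_tr]])
  }
  two_layer_network(edges, backbone = net$backbone, transcript = transcript)
}

#' Test balance of the sign-flipped backbone
#'
#' The score matrix Q is the signed Laplacian of the backbone subgraph with
#' all edge signs flipped (written Gb-). Its smallest eigenvalue vanishes
#' exactly when Gb- is balanced, i.e. every cycle has a positive sign
#' product, equivalently the nodes split into two groups with all
#' within-group edges positive and all crossing edges negative (in Gb-).
#' Only on such backbones can a nonzero backbone profile have score zero.
#'
#' The test is combinatorial (two-coloring by breadth-first search over a
#' spanning structure, then checking every edge), independent of any
#' eigen-decomposition.
#'
#' @param net A [two_layer_network()].
#' @return `TRUE` if Gb- is balanced. Acyclic backbones are always balanced.
#' @examples
#' is_balanced(toy_network()) # single edge, acyclic: TRUE
#' @export
is_balanced <- function(net) {
  stopifnot(inherits(net, "two_layer_network"))
  eb <- backbone_edges(net)
  eb <- dplyr::filter(eb, .data$source != .data$target)
  # collapse reciprocal duplicates; contradictory signs make Gb- unbalanced
  key <- paste(pmin(eb$source, eb$target), pmax(eb$source, eb$target), sep = "\r")
  sgn <- vapply(split(-eb$sign, key), function(s) {
    if (length(unique(s)) > 1) NA_integer_ else s[[1]]
  }, integer(1))
  if (anyNA(sgn)) return(FALSE)
  ends <- strsplit(names(sgn), "\r", fixed = TRUE)
  u <- vapply(ends, `[[`, character(1), 1)
  v <- vapply(ends, `[[`, character(1), 2)

  color <- setNames(rep(NA_integer_, length(net$backbone)), net$backbone)
  adj <- split(seq_along(u), u)
  adj2 <- split(seq_along(v), v)
  for (root in net$backbone) {
    if (!is.na(color[[root]])) next
    color[[root]] <- 1L
    queue <- root
    while (length(queue) > 0) {
      x <- queue[[1]]; queue <- queue[-1]
      idx <- c(adj[[x]], adj2[[x]])
      for (i in idx) {
        y <- if (u[[i]] == x) v[[i]] else u[[i]]
        want <- if (sgn[[i]] > 0) color[[x]] else -color[[x]]
        if (is.na(color[[y]])) {
          color[[y]] <- want
          queue <- c(queue, y)
        } else if (color[[y]] != want) {
          return(FALSE)
        }
      }
    }
  }
  TRUE
}

#' A minimal two-layer example network
#'
#' Two backbone nodes `a -> b` (positive) with one downstream gene each
#' (`a -> g1`, `b -> g2`, both positive, all weights 1). Small enough that
#' every matrix in the pipeline can be written down by hand.
#'
#' @return A [two_layer_network()].
#' @export
toy_network <- function() {
  two_layer_network(tibble::tibble(
    source = c("a", "a", "b"),
    target = c("b", "g1", "g2"),
    sign = c(1L, 1L, 1L),
    weight = 1,
    layer_target = c("backbone", "transcript", "transcript")
  ))
}
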