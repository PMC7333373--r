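# Epistasis network assembly and serialization. Nodes carry the
# mutual-information main effect of each predictor, edges the pairwise
# information gain, and hyperedges the three-variable gain; each element
# keeps its permutation p-value and Bonferroni class so renderers can
# size nodes by MI, thicken edges by IG and color them by significance.

#' Assemble an epistasis network from screen results
#'
#' @param main_results [run_screen()] output with `order = 1` (nodes).
#' @param pair_results [run_screen()] output with `order = 2` (edges).
#' @param triple_results Optional `order = 3` output (hyperedges).
#' @return Object of class `epistasis_network` with data.frames
#'   `nodes`, `edges`, `hyperedges` and a `thresholds` list per family.
#' @export
build_network <- function(main_results, pair_results,
                          triple_results = NULL) {
  nodes <- data.frame(variable = main_results$v1,
                      mi_bits = main_results$bits,
                      mi_pct = main_results$pct,
                      p = main_results$p, class = main_results$class,
                      stringsAsFactors = FALSE)
  edge_vars <- unique(c(pair_results$v1, pair_results$v2,
                        triple_results$v1, triple_results$v2,
                        triple_results$v3))
  unknown <- setdiff(edge_vars, nodes$variable)
  if (length(unknown)) {
    stop("edge endpoints missing from node set: ",
         paste(unknown, collapse = ", "))
  }
  edges <- data.frame(v1 = pair_results$v1, v2 = pair_results$v2,
                      ig_bits = pair_results$bits,
                      ig_pct = pair_results$pct,
                      p = pair_results$p, class = pair_results$class,
                      stringsAsFactors = FALSE)
  hyperedges <- if (!is.null(triple_results)) {
    data.frame(v1 = triple_results$v1, v2 = triple_results$v2,
               v3 = triple_results$v3, ig_bits = triple_results$bits,
               ig_pct = triple_results$pct, p = triple_results$p,
               class = triple_results$class, stringsAsFactors = FALSE)
  } else {
    data.frame(v1 = character(0), v2 = character(0), v3 = character(0),
               ig_bits = numeric(0), ig_pct = numeric(0), p = numeric(0),
               class = character(0), stringsAsFactors = FALSE)
  }
  thr <- function(res) {
    f <- attr(res, "family")
    if (is.null(f)) NULL
    else f[c("m", "B", "threshold_significant", "threshold_suggestive",
             "printed_significant", "printed_suggestive")]
  }
  structure(list(nodes = nodes, edges = edges, hyperedges = hyperedges,
                 thresholds = list(main = thr(main_results),
                                   pairwise = thr(pair_results),
                                   threeway = thr(triple_results))),
            class = "epistasis_network")
}

#' @export
print.epistasis_network <- function(x, ...) {
  cat(sprintf(
    "epistasis_network: %d nodes, %d edges (%d classed), %d hyperedges (%d classed)\n",
    nrow(x$nodes), nrow(x$edges), sum(x$edges$class != "null"),
    nrow(x$hyperedges), sum(x$hyperedges$class != "null")))
  invisible(x)
}

.network_igraph <- function(network) {
  g <- igraph::graph_from_data_frame(
    network$edges[, c("v1", "v2", "ig_bits", "ig_pct", "p", "class")],
    directed = FALSE, vertices = network$nodes)
  igraph::E(g)$weight <- network$edges$ig_bits
  g
}

#' Serialize an epistasis network
#'
#' JSON preserves the full structure (including hyperedges) and
#' round-trips through [import_network()]; GraphML and DOT carry the
#' nodes and pairwise edges with their weights and significance classes
#' as attributes (hyperedges have no standard encoding in either
#' format).
#'
#' @param network An `epistasis_network`.
#' @param path Output file path.
#' @param format `"json"`, `"graphml"` or `"dot"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(network, path, format = c("json", "graphml",
                                                     "dot")) {
  format <- match.arg(format)
  if (format == "json") {
    payload <- list(nodes = network$nodes, edges = network$edges,
                    hyperedges = network$hyperedges,
                    thresholds = network$thresholds)
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, dataframe = "rows")
  } else {
    g <- .network_igraph(network)
    igraph::write_graph(g, path, format = format)
  }
  invisible(path)
}

#' Read back a JSON-serialized epistasis network
#'
#' @param path Path written by [export_network()] with `format =
#'   "json"`.
#' @return An `epistasis_network`.
#' @export
import_network <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  empty_hyper <- data.frame(v1 = character(0), v2 = character(0),
                            v3 = character(0), ig_bits = numeric(0),
                            ig_pct = numeric(0), p = numeric(0),
                            class = character(0), stringsAsFactors = FALSE)
  hyper <- if (length(payload$hyperedges)) payload$hyperedges else empty_hyper
  structure(list(nodes = payload$nodes, edges = payload$edges,
                 hyperedges = hyper, thresholds = payload$thresholds),
            class = "epistasis_network")
}
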