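#' Read a metabolite interaction network from an edge list
#'
#' Two-column text (tab- or comma-separated, optional header), one
#' undirected edge per row. Self-loops and duplicate edges are removed:
#' the network is a simple graph.
#'
#' @param path Edge-list file path.
#' @param sep Field separator (default tab).
#'
#' @return An `igraph` undirected simple graph.
#' @export
read_edge_list <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = sep, header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("from", "to"),
                          strip.white = TRUE)
  if (tolower(df$from[1L]) %in% c("from", "nodea", "node_a", "source")) {
    df <- df[-1L, , drop = FALSE]
  }
  g <- igraph::graph_from_data_frame(df, directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Node degrees of an interaction network
#'
#' @param net An `igraph` graph (see [read_edge_list()]) or a two-column
#'   `data.frame` edge list.
#'
#' @return List with `degrees` (named integer vector, one per node) and
#'   `mean_degree` (network-wide mean).
#' @export
#' @examples
#' node_degrees(data.frame(from = c("A", "B", "C"), to = c("B", "C", "A")))
node_degrees <- function(net) {
  if (is.data.frame(net)) {
    net <- igraph::simplify(igraph::graph_from_data_frame(net,
                                                          directed = FALSE))
  }
  stopifnot(igraph::is_igraph(net))
  d <- igraph::degree(net, loops = FALSE)
  list(degrees = d, mean_degree = if (length(d)) mean(d) else NA_real_)
}

#' Select central-node biomarkers of metapathway state (BMS)
#'
#' Ranks metabolites by degree centrality, descending, ties broken
#' alphabetically (deterministic), and returns the top of the ranking —
#' the highest-centrality nodes of a metabolite-metabolite interaction
#' network, used as state biomarkers of the pathway set it represents.
#'
#' @param degrees Named numeric vector of node degrees (as in
#'   `node_degrees(net)$degrees`), or the list returned by [node_degrees()].
#' @param top_k Number of top-ranked metabolites to return.
#' @param min_degree Alternatively, return all nodes with degree >=
#'   `min_degree`. Exactly one of `top_k`/`min_degree` must be given.
#'
#' @return A `data.frame` with columns `metabolite`, `degree`, `rank`,
#'   in ranking order.
#' @export
select_central <- function(degrees, top_k = NULL, min_degree = NULL) {
  if (is.list(degrees) && !is.null(degrees$degrees)) degrees <- degrees$degrees
  if (!length(degrees)) stop("empty degree map", call. = FALSE)
  if (is.null(names(degrees)) || any(!nzchar(names(degrees)))) {
    stop("'degrees' must be named by metabolite", call. = FALSE)
  }
  if (is.null(top_k) == is.null(min_degree)) {
    stop("give exactly one of 'top_k' or 'min_degree'", call. = FALSE)
  }
  o <- order(-degrees, names(degrees))
  ranked <- data.frame(metabolite = names(degrees)[o],
                       degree = unname(degrees)[o],
                       rank = seq_along(o),
                       stringsAsFactors = FALSE)
  if (!is.null(top_k)) {
    if (top_k > nrow(ranked)) {
      stop(sprintf("top_k (%d) exceeds node count (%d)", top_k, nrow(ranked)),
           call. = FALSE)
    }
    return(ranked[seq_len(top_k), , drop = FALSE])
  }
  out <- ranked[ranked$degree >= min_degree, , drop = FALSE]
  rownames(out) <- NULL
  out
}
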