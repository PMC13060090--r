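#' Construct a bipartite metabolic network
#'
#' A metabolic network is an undirected bipartite graph whose two node types
#' are enzyme classes (EC numbers, e.g. \code{"2.5.1.49"}) and metabolites
#' (compound identifiers, e.g. \code{"C00073"}). Every edge joins one EC node
#' to one metabolite node (a reaction's substrate or product).
#'
#' @param edges a two-column data frame (or matrix) with columns
#'   \code{ec_id} and \code{metabolite_id}. Duplicate rows collapse to a
#'   single edge; ids are whitespace-trimmed and case-sensitive.
#' @param isolated_ec optional character vector of EC node ids to include
#'   without edges (used when filtering strips all edges from an EC).
#' @param isolated_met optional character vector of metabolite node ids to
#'   include without edges.
#' @return an object of class \code{metabolic_network} with elements
#'   \code{nodes} (data frame: \code{node_id}, \code{node_type}) and
#'   \code{edges} (data frame: \code{ec_id}, \code{metabolite_id}).
#' @export
metabolic_network <- function(edges, isolated_ec = character(),
                              isolated_met = character()) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!all(c("ec_id", "metabolite_id") %in% names(edges))) {
    names(edges)[1:2] <- c("ec_id", "metabolite_id")
  }
  edges$ec_id <- trimws(as.character(edges$ec_id))
  edges$metabolite_id <- trimws(as.character(edges$metabolite_id))
  if (nrow(edges) > 0 && any(edges$ec_id == "" | edges$metabolite_id == "")) {
    stop("empty node id in edge list")
  }
  edges <- unique(edges[, c("ec_id", "metabolite_id")])
  if (any(edges$ec_id == edges$metabolite_id)) {
    stop("self-loop: identical id in both columns of an edge")
  }
  ec <- unique(c(edges$ec_id, trimws(isolated_ec)))
  met <- unique(c(edges$metabolite_id, trimws(isolated_met)))
  both <- intersect(ec, met)
  if (length(both) > 0) {
    stop("bipartiteness violated: id(s) appear as both EC and metabolite: ",
         paste(utils::head(both, 5), collapse = ", "))
  }
  ec <- ec[ec != ""]
  met <- met[met != ""]
  nodes <- data.frame(
    node_id = c(ec, met),
    node_type = c(rep("EC", length(ec)), rep("METABOLITE", length(met))),
    stringsAsFactors = FALSE
  )
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "metabolic_network")
}

#' Read a metabolic network from a tab-separated edge list
#'
#' The file must be tab-separated with header columns \code{ec_id} and
#' \code{metabolite_id}. Duplicate rows collapse to one edge.
#'
#' @param path path to the TSV edge list.
#' @return a \code{\link{metabolic_network}}.
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stop("edge list not found: ", path)
  raw <- readLines(path, warn = FALSE)
  raw <- raw[nzchar(raw)]
  if (length(raw) < 1) stop("empty edge list: ", path)
  header <- strsplit(raw[1], "\t", fixed = TRUE)[[1]]
  ic <- match(c("ec_id", "metabolite_id"), trimws(header))
  if (any(is.na(ic))) {
    stop("edge list header must contain columns 'ec_id' and 'metabolite_id': ",
         path)
  }
  if (length(raw) < 2) stop("edge list has a header but no rows: ", path)
  rows <- strsplit(raw[-1], "\t", fixed = TRUE)
  bad <- which(vapply(rows, length, 1L) < max(ic))
  if (length(bad) > 0) {
    stop("malformed edge-list row (missing column) at line ", bad[1] + 1,
         " of ", path)
  }
  edges <- data.frame(
    ec_id = vapply(rows, `[[`, "", ic[1]),
    metabolite_id = vapply(rows, `[[`, "", ic[2]),
    stringsAsFactors = FALSE
  )
  metabolic_network(edges)
}

#' Write a metabolic network as a tab-separated edge list
#'
#' @param net a \code{\link{metabolic_network}}.
#' @param path output path. Isolated nodes are not representable in an edge
#'   list and are dropped with a message.
#' @return \code{path}, invisibly.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "metabolic_network"))
  linked <- unique(c(net$edges$ec_id, net$edges$metabolite_id))
  iso <- setdiff(net$nodes$node_id, linked)
  if (length(iso) > 0) {
    message(length(iso), " isolated node(s) not representable in edge list")
  }
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Convert a metabolic network to an igraph object
#'
#' Vertices carry a \code{node_type} attribute (\code{"EC"} or
#' \code{"METABOLITE"}).
#'
#' @param net a \code{\link{metabolic_network}}.
#' @return an undirected \code{igraph} graph.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "metabolic_network"))
  g <- igraph::graph_from_data_frame(
    net$edges, directed = FALSE,
    vertices = net$nodes[, c("node_id", "node_type")]
  )
  g
}

#' Node types of a metabolic network
#'
#' @param net a \code{\link{metabolic_network}}.
#' @return named character vector mapping node id to \code{"EC"} /
#'   \code{"METABOLITE"}.
#' @export
node_types <- function(net) {
  stats::setNames(net$nodes$node_type, net$nodes$node_id)
}

#' Remove currency metabolites from a network
#'
#' Ubiquitous high-degree compounds (water, ATP, ...) connect otherwise
#' unrelated reactions and are removed to keep the topology informative.
#' Exactly one of \code{max_degree} or \code{explicit_list} must be given:
#' either all metabolites whose degree exceeds \code{max_degree}, or the
#' named metabolites, are removed together with their incident edges.
#' EC nodes are never removed; ECs left without edges are retained as
#' isolated nodes (and reported via attribute \code{"isolated_ec"}).
#'
#' @param net a \code{\link{metabolic_network}}.
#' @param max_degree positive integer degree cutoff (metabolites with degree
#'   strictly greater are removed).
#' @param explicit_list character vector of metabolite ids to remove.
#' @return a filtered \code{metabolic_network}; attribute \code{"removed"}
#'   lists the removed metabolite ids, attribute \code{"isolated_ec"} the EC
#'   nodes left without edges.
#' @export
filter_currency_metabolites <- function(net, max_degree = NULL,
                                        explicit_list = NULL) {
  stopifnot(inherits(net, "metabolic_network"))
  if (is.null(max_degree) == is.null(explicit_list)) {
    stop("provide exactly one of max_degree or explicit_list")
  }
  types <- node_types(net)
  if (!is.null(explicit_list)) {
    explicit_list <- trimws(explicit_list)
    known <- explicit_list[explicit_list %in% names(types)]
    if (any(types[known] == "EC")) {
      stop("explicit_list contains EC id(s): ",
           paste(known[types[known] == "EC"], collapse = ", "))
    }
    remove <- known
  } else {
    stopifnot(max_degree >= 1)
    deg <- table(net$edges$metabolite_id)
    remove <- names(deg)[deg > max_degree]
  }
  keep <- !(net$edges$metabolite_id %in% remove)
  edges <- net$edges[keep, , drop = FALSE]
  ec_all <- net$nodes$node_id[net$nodes$node_type == "EC"]
  met_keep <- setdiff(net$nodes$node_id[net$nodes$node_type == "METABOLITE"],
                      remove)
  out <- metabolic_network(
    edges,
    isolated_ec = setdiff(ec_all, edges$ec_id),
    isolated_met = setdiff(met_keep, edges$metabolite_id)
  )
  attr(out, "removed") <- remove
  attr(out, "isolated_ec") <- setdiff(ec_all, edges$ec_id)
  out
}

#' Connected components of a metabolic network
#'
#' @param net a \code{\link{metabolic_network}}.
#' @return list of character vectors (node-id sets), one per component,
#'   sorted by decreasing size, ties broken by the lexicographically
#'   smallest member. Members of each component are sorted.
#' @export
connected_components <- function(net) {
  stopifnot(inherits(net, "metabolic_network"))
  if (nrow(net$nodes) == 0) return(list())
  g <- as_igraph(net)
  cmp <- igraph::components(g)
  comps <- split(names(cmp$membership), cmp$membership)
  comps <- lapply(comps, sort)
  mins <- vapply(comps, `[[`, "", 1)
  ord <- order(-lengths(comps), mins)
  unname(comps[ord])
}

#' Nodes reachable by short paths within an induced subgraph
#'
#' Breadth-first search from \code{source} restricted to the subgraph induced
#' by \code{allowed}, returning every allowed node reachable by a path of
#' strictly fewer than \code{max_len} edges (the source itself is at
#' distance 0).
#'
#' @param net a \code{\link{metabolic_network}}.
#' @param allowed character vector of node ids inducing the subgraph.
#' @param source a node id, must be in \code{allowed}.
#' @param max_len positive integer; paths must have < \code{max_len} edges.
#' @return character vector of reachable node ids (including source).
#' @export
bfs_reachable <- function(net, allowed, source, max_len) {
  stopifnot(inherits(net, "metabolic_network"), max_len >= 1)
  allowed <- unique(allowed)
  if (!(source %in% allowed)) stop("source not in allowed set: ", source)
  allowed <- intersect(allowed, net$nodes$node_id)
  g <- as_igraph(net)
  sub <- igraph::induced_subgraph(g, allowed)
  d <- igraph::distances(sub, v = source, to = igraph::V(sub))
  sort(colnames(d)[d[1, ] < max_len])
}

#' @export
print.metabolic_network <- function(x, ...) {
  n_ec <- sum(x$nodes$node_type == "EC")
  n_met <- sum(x$nodes$node_type == "METABOLITE")
  cat("Bipartite metabolic network\n")
  cat(sprintf("  %d EC nodes, %d metabolite nodes, %d edges\n",
              n_ec, n_met, nrow(x$edges)))
  invisible(x)
}

#' Export a metabolic network to GraphML
#'
#' @param net a \code{\link{metabolic_network}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}
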