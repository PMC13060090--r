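#' Cluster anchors by co-membership
#'
#' Average-linkage hierarchical clustering of the anchor nodes on the
#' distance \code{1 - M}, cutting the dendrogram at height \code{cut}
#' (default 0.8): merges occur while the average distance is at most
#' \code{cut}. The height cut lets a cluster bridge anchors separated by a
#' non-anchor gap (whose pairwise co-membership is moderate), which is why
#' clusters need not induce connected subgraphs and are subsequently
#' completed by Steiner trees. Set \code{cut_is_distance = FALSE} to read
#' \code{cut} as a similarity threshold instead (merges only at average
#' co-membership \code{>= cut}, i.e. height \code{1 - cut}); that reading is
#' far stricter and yields small, tight clusters. Anchors are ordered
#' lexicographically before clustering so ties break deterministically.
#' Singleton clusters are returned but flagged.
#'
#' @param M an anchor-filtered \code{\link{co_membership}} matrix.
#' @param cut dendrogram cut in (0, 1); default 0.8.
#' @param cut_is_distance interpret \code{cut} as a height on \code{1 - M}
#'   (default) rather than a similarity threshold.
#' @return list of objects of class \code{anchor_cluster}, each a list with
#'   \code{anchors} (character) and \code{singleton} (logical). Ordered by
#'   decreasing size, ties by smallest member id.
#' @export
cluster_anchors <- function(M, cut = 0.8, cut_is_distance = TRUE) {
  stopifnot(inherits(M, "co_membership"), cut > 0, cut < 1)
  ids <- sort(M$node_ids)
  if (length(ids) == 0) return(list())
  h <- if (cut_is_distance) cut else 1 - cut
  if (length(ids) == 1) {
    grp <- stats::setNames(1L, ids)
  } else {
    V <- M$values[ids, ids]
    V <- (V + t(V)) / 2            # guard against numeric asymmetry
    d <- stats::as.dist(1 - V)
    hc <- stats::hclust(d, method = "average")
    # average linkage is monotone; guard against float round-off inversions
    hc$height <- cummax(hc$height)
    grp <- stats::cutree(hc, h = h)
  }
  cl <- split(names(grp), grp)
  cl <- lapply(cl, sort)
  mins <- vapply(cl, `[[`, "", 1)
  cl <- cl[order(-lengths(cl), mins)]
  lapply(unname(cl), function(a) {
    structure(list(anchors = a, singleton = length(a) == 1),
              class = "anchor_cluster")
  })
}

#' Complete an anchor cluster into a connected module
#'
#' Shortest-path Steiner-tree heuristic: every anchor starts as its own
#' subtree; repeatedly, the minimum shortest-path distance between any two
#' subtrees in the full network is found, one path is chosen uniformly at
#' random among all minimum-length inter-subtree shortest paths, its nodes
#' are added and the subtrees merged, until a single tree remains. The
#' module is the subgraph of the network induced by all collected nodes
#' (not necessarily a tree).
#'
#' @param net a \code{\link{metabolic_network}}.
#' @param anchors character vector of anchor node ids (or an
#'   \code{anchor_cluster}); must lie in one connected component.
#' @param seed optional integer seed for the random path choice.
#' @param max_paths cap on enumerated minimum-length paths per merge step
#'   (default 1000); selection is uniform within the cap.
#' @return an object of class \code{metabolic_module}: list with
#'   \code{nodes}, \code{edges} (induced edge data frame), \code{anchors},
#'   \code{tree_edges} (the heuristic tree's edge count) and \code{seed}.
#' @export
steiner_complete <- function(net, anchors, seed = NULL, max_paths = 1000) {
  stopifnot(inherits(net, "metabolic_network"))
  if (inherits(anchors, "anchor_cluster")) anchors <- anchors$anchors
  anchors <- sort(unique(anchors))
  if (length(anchors) == 0) stop("empty anchor set")
  missing <- setdiff(anchors, net$nodes$node_id)
  if (length(missing) > 0) {
    stop("anchor(s) not in network: ", paste(missing, collapse = ", "))
  }
  comps <- connected_components(net)
  in_comp <- vapply(comps, function(cc) any(anchors %in% cc), TRUE)
  if (sum(in_comp) > 1) {
    stop("anchors span multiple connected components")
  }
  if (!is.null(seed)) {
    old <- local_seed(seed)
    on.exit(restore_seed(old), add = TRUE)
  }
  g <- as_igraph(net)
  subtrees <- lapply(anchors, identity)     # each a character vector
  tree_edges <- character(0)                # "u|v" keys, u < v
  while (length(subtrees) > 1) {
    members <- unlist(subtrees)
    D <- igraph::distances(g, v = members, to = members)
    tree_of <- rep(seq_along(subtrees), lengths(subtrees))
    # minimum inter-subtree shortest-path distance
    same <- outer(tree_of, tree_of, "==")
    D[same] <- Inf
    L <- min(D)
    if (!is.finite(L)) stop("subtrees are disconnected in the network")
    idx <- which(D == L, arr.ind = TRUE)
    # enumerate all minimum-length paths between endpoint pairs (u < v once)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    paths <- list()
    for (r in seq_len(nrow(idx))) {
      u <- members[idx[r, 1]]
      v <- members[idx[r, 2]]
      sp <- igraph::all_shortest_paths(g, from = u, to = v)$vpaths
      for (pp in sp) {
        paths[[length(paths) + 1]] <- names(pp)
        if (length(paths) >= max_paths) break
      }
      if (length(paths) >= max_paths) break
    }
    pick <- paths[[sample.int(length(paths), 1)]]
    pe <- cbind(pick[-length(pick)], pick[-1])
    tree_edges <- union(tree_edges,
                        paste(pmin(pe[, 1], pe[, 2]),
                              pmax(pe[, 1], pe[, 2]), sep = "|"))
    touched <- vapply(subtrees, function(s) any(pick %in% s), TRUE)
    merged <- unique(c(unlist(subtrees[touched]), pick))
    subtrees <- c(subtrees[!touched], list(merged))
  }
  nodes <- sort(unique(subtrees[[1]]))
  keep <- net$edges$ec_id %in% nodes & net$edges$metabolite_id %in% nodes
  structure(
    list(nodes = nodes, edges = net$edges[keep, , drop = FALSE],
         anchors = anchors, tree_edges = tree_edges, seed = seed),
    class = "metabolic_module"
  )
}

#' Build modules from anchor clusters
#'
#' Completes every cluster into a connected module via
#' \code{\link{steiner_complete}}, computes per-module anchor counts and the
#' mean anchor p-value, and flags validity (at least \code{min_anchors}
#' anchors). Modules are sorted by ascending mean anchor p-value.
#'
#' @param net a \code{\link{metabolic_network}}.
#' @param clusters list of \code{anchor_cluster} (from
#'   \code{\link{cluster_anchors}}).
#' @param an the annotated network providing anchor p-values.
#' @param min_anchors minimum anchors for a valid module (default 2).
#' @param seed master seed; each cluster gets its own substream.
#' @return an object of class \code{module_set}: list of
#'   \code{metabolic_module} objects (each gaining \code{anchors_ec},
#'   \code{anchors_met}, \code{p_hat}, \code{valid}, \code{module_id}),
#'   with the generating parameters attached.
#' @export
build_modules <- function(net, clusters, an, min_anchors = 2, seed = 1L) {
  stopifnot(inherits(net, "metabolic_network"),
            inherits(an, "annotated_network"))
  types <- node_types(net)
  seeds <- if (length(clusters) > 0) spawn_seeds(seed, length(clusters)) else integer(0)
  mods <- vector("list", length(clusters))
  for (i in seq_along(clusters)) {
    m <- steiner_complete(net, clusters[[i]], seed = seeds[i])
    m$anchors_ec <- m$anchors[types[m$anchors] == "EC"]
    m$anchors_met <- m$anchors[types[m$anchors] == "METABOLITE"]
    m$p_hat <- mean(an$p[m$anchors])
    m$valid <- length(m$anchors) >= min_anchors
    mods[[i]] <- m
  }
  if (length(mods) > 0) {
    mods <- mods[order(vapply(mods, `[[`, 1, "p_hat"))]
    for (i in seq_along(mods)) mods[[i]]$module_id <- i
  }
  structure(list(modules = mods, min_anchors = min_anchors, seed = seed),
            class = "module_set")
}

#' @export
print.metabolic_module <- function(x, ...) {
  cat(sprintf("Metabolic module: %d nodes, %d edges, %d anchors",
              length(x$nodes), nrow(x$edges), length(x$anchors)))
  if (!is.null(x$p_hat)) {
    cat(sprintf(" (N_EC = %d, N_met = %d, mean anchor p = %.3g%s)",
                length(x$anchors_ec), length(x$anchors_met), x$p_hat,
                if (isTRUE(x$valid)) "" else ", not valid"))
  }
  cat("\n")
  invisible(x)
}

#' @export
print.module_set <- function(x, ...) {
  cat(sprintf("Module set: %d module(s), %d valid\n",
              length(x$modules),
              sum(vapply(x$modules, `[[`, TRUE, "valid"))))
  for (m in x$modules) print(m)
  invisible(x)
}

#' @export
as.data.frame.module_set <- function(x, ...) {
  if (length(x$modules) == 0) {
    return(data.frame(module_id = integer(0), n_nodes = integer(0),
                      n_ec_anchors = integer(0), n_met_anchors = integer(0),
                      p_hat = numeric(0), valid = logical(0)))
  }
  do.call(rbind, lapply(x$modules, function(m) {
    data.frame(module_id = m$module_id, n_nodes = length(m$nodes),
               n_ec_anchors = length(m$anchors_ec),
               n_met_anchors = length(m$anchors_met),
               p_hat = m$p_hat, valid = m$valid,
               p_perm = m$p_perm %||% NA_real_, q = m$q %||% NA_real_,
               stringsAsFactors = FALSE)
  }))
}

#' @export
summary.module_set <- function(object, ...) {
  df <- as.data.frame(object)
  cat(sprintf("Module set: %d module(s), %d valid\n", nrow(df),
              sum(df$valid)))
  if (nrow(df) > 0) print(df, row.names = FALSE)
  invisible(df)
}
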