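#' Generate a random bipartite metabolic network
#'
#' Each metabolite is connected to \code{Poisson(mean_met_degree) + 1}
#' distinct, uniformly chosen EC nodes, so the graph is simple and bipartite
#' by construction. The default density (2.5 edges per metabolite) is typical
#' of curated EC-metabolite networks after currency-metabolite removal.
#'
#' @param n_ec number of EC nodes (>= 1).
#' @param n_met number of metabolite nodes (>= 1).
#' @param mean_met_degree mean extra degree per metabolite (default 2.5,
#'   i.e. expected degree 1 + 2.5 truncated at \code{n_ec}).
#' @param seed integer seed; the same seed reproduces the same network.
#' @return a \code{\link{metabolic_network}} with nodes \code{EC1..}, and
#'   \code{M1..}.
#' @export
generate_network <- function(n_ec, n_met, mean_met_degree = 2.5, seed = 1L) {
  stopifnot(n_ec >= 1, n_met >= 1, mean_met_degree >= 0)
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  ecs <- paste0("EC", seq_len(n_ec))
  mets <- paste0("M", seq_len(n_met))
  deg <- pmin(stats::rpois(n_met, mean_met_degree) + 1L, n_ec)
  edges <- do.call(rbind, lapply(seq_len(n_met), function(j) {
    data.frame(ec_id = sample(ecs, deg[j]), metabolite_id = mets[j],
               stringsAsFactors = FALSE)
  }))
  metabolic_network(edges, isolated_ec = setdiff(ecs, edges$ec_id))
}

#' Plant a condition-associated module in a network
#'
#' Chooses a connected node set of \code{module_size} nodes by a seeded
#' random growth within one connected component; planted nodes draw their
#' p-value from Beta(\code{a_signal}, 1) (signal), all other nodes from
#' Uniform(0, 1) (noise). Each EC (metabolite) node is then retained as
#' observed with probability \code{coverage_ec} (\code{coverage_met}) —
#' except, when \code{boost_planted} is \code{TRUE} (the default), planted
#' EC nodes are always observed and planted metabolites are observed with
#' probability \code{max(coverage_met, met_boost)}. The boost deliberately
#' deviates from uniform coverage: at realistic metabolite coverage of a few
#' percent, recovery of planted metabolite anchors would be impossible at
#' benchmark scale, and the benchmark must separate algorithmic failure from
#' data starvation.
#'
#' @param net a \code{\link{metabolic_network}}.
#' @param module_size number of planted nodes; must not exceed the largest
#'   connected component.
#' @param a_signal Beta shape of the planted p-values, in (0, 1).
#' @param coverage_ec probability an EC node is observed.
#' @param coverage_met probability a metabolite node is observed.
#' @param seed integer seed.
#' @param boost_planted keep planted nodes observable (default TRUE).
#' @param met_boost minimum observation probability for planted metabolites
#'   when boosted (default 0.5).
#' @return list with \code{ec_scores}, \code{met_scores} (score tables of
#'   the observed nodes) and \code{truth}, an object of class
#'   \code{planted_truth} (fields \code{module_nodes}, \code{a_signal},
#'   \code{coverage_ec}, \code{coverage_met}, \code{seed}).
#' @export
plant_signal <- function(net, module_size, a_signal, coverage_ec,
                         coverage_met, seed = 1L, boost_planted = TRUE,
                         met_boost = 0.5) {
  stopifnot(inherits(net, "metabolic_network"),
            a_signal > 0, a_signal < 1,
            coverage_ec >= 0, coverage_ec <= 1,
            coverage_met >= 0, coverage_met <= 1)
  comps <- connected_components(net)
  big <- comps[lengths(comps) >= module_size]
  if (length(big) == 0) {
    stop("no connected component of size >= ", module_size)
  }
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)

  comp <- big[[sample.int(length(big), 1)]]
  # seeded random walk within the chosen component; the set of distinct
  # visited nodes is the planted module (connected by construction)
  adj <- adjacency_list(net)
  cur <- sample(comp, 1)
  planted <- cur
  while (length(planted) < module_size) {
    cur <- sample(adj[[cur]], 1)
    planted <- union(planted, cur)
  }
  planted <- sort(planted)

  types <- node_types(net)
  ids <- net$nodes$node_id
  is_planted <- ids %in% planted
  p <- stats::runif(length(ids))
  p[is_planted] <- stats::runif(sum(is_planted))^(1 / a_signal)

  keep_prob <- ifelse(types[ids] == "EC", coverage_ec, coverage_met)
  if (boost_planted) {
    keep_prob[is_planted & types[ids] == "EC"] <- 1
    keep_prob[is_planted & types[ids] == "METABOLITE"] <-
      pmax(coverage_met, met_boost)
  }
  observed <- stats::runif(length(ids)) < keep_prob

  mk <- function(ty) {
    sel <- observed & types[ids] == ty
    score_table(ids[sel], ty, p[sel])
  }
  truth <- structure(
    list(module_nodes = planted, a_signal = a_signal,
         coverage_ec = coverage_ec, coverage_met = coverage_met,
         seed = seed),
    class = "planted_truth"
  )
  list(ec_scores = mk("EC"), met_scores = mk("METABOLITE"), truth = truth)
}

# Internal: adjacency list of a metabolic network.
adjacency_list <- function(net) {
  ids <- net$nodes$node_id
  adj <- stats::setNames(vector("list", length(ids)), ids)
  for (i in seq_len(nrow(net$edges))) {
    e <- net$edges$ec_id[i]
    m <- net$edges$metabolite_id[i]
    adj[[e]] <- c(adj[[e]], m)
    adj[[m]] <- c(adj[[m]], e)
  }
  adj
}

#' Recovery metrics against a planted truth
#'
#' @param predicted a \code{module_set}, \code{module_discovery}, or list of
#'   \code{metabolic_module} objects.
#' @param truth a \code{planted_truth}.
#' @return named numeric: \code{best_jaccard} (max over predicted modules of
#'   |pred ∩ truth| / |pred ∪ truth|), and \code{precision} / \code{recall}
#'   of that best module. All 0 when nothing was predicted.
#' @export
recovery_metrics <- function(predicted, truth) {
  stopifnot(inherits(truth, "planted_truth"))
  if (inherits(predicted, "module_discovery")) predicted <- predicted$modules
  if (inherits(predicted, "module_set")) predicted <- predicted$modules
  if (length(predicted) == 0) {
    return(c(best_jaccard = 0, precision = 0, recall = 0))
  }
  tset <- truth$module_nodes
  jac <- vapply(predicted, function(m) {
    length(intersect(m$nodes, tset)) / length(union(m$nodes, tset))
  }, 1)
  best <- predicted[[which.max(jac)]]
  inter <- length(intersect(best$nodes, tset))
  c(best_jaccard = max(jac),
    precision = inter / length(best$nodes),
    recall = inter / length(tset))
}

#' Write a synthetic study to disk
#'
#' Writes the generated edge list, the two score tables and the planted
#' truth (TSV of planted node ids) into a directory, as consumed by the
#' command-line pipeline.
#'
#' @param net a \code{\link{metabolic_network}}.
#' @param sim result of \code{\link{plant_signal}}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_synthetic_study <- function(net, sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_edge_list(net, file.path(dir, "network.tsv"))
  write_score_table(sim$ec_scores, file.path(dir, "ec_scores.tsv"))
  write_score_table(sim$met_scores, file.path(dir, "met_scores.tsv"))
  utils::write.table(
    data.frame(node_id = sim$truth$module_nodes, stringsAsFactors = FALSE),
    file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(dir)
}
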