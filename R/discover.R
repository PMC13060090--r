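#' Discover candidate modules on an annotated network
#'
#' Runs the identification stages in order: anchor selection (observed nodes
#' with p below their type's mixture threshold), Monte-Carlo co-membership
#' estimation between anchors, average-linkage clustering of the anchors,
#' and Steiner completion of each cluster into a connected module.
#'
#' @param an an annotated network (\code{\link{project_scores}}).
#' @param fits per-type mixture fits (\code{\link{fit_bum_per_type}}).
#' @param cfg a \code{\link{sampling_config}}; its seed drives both the
#'   co-membership iterations and the random Steiner path choices.
#' @param cut dendrogram cut for anchor clustering (default 0.8).
#' @param cut_is_distance see \code{\link{cluster_anchors}}.
#' @param min_anchors minimum anchors for a valid module (default 2).
#' @return an object of class \code{module_discovery}: list with
#'   \code{anchors}, \code{M} (\code{co_membership}), \code{clusters} and
#'   \code{modules} (a \code{module_set}).
#' @examples
#' net <- generate_network(n_ec = 40, n_met = 40, seed = 7)
#' sim <- plant_signal(net, module_size = 8, a_signal = 0.1,
#'                     coverage_ec = 1, coverage_met = 1, seed = 7)
#' an <- project_scores(net, sim$ec_scores, sim$met_scores)
#' fits <- fit_bum_per_type(an)
#' d <- discover_modules(an, fits, sampling_config(n_iter = 200, seed = 7))
#' d$modules
#' @export
discover_modules <- function(an, fits, cfg = sampling_config(), cut = 0.8,
                             cut_is_distance = TRUE, min_anchors = 2) {
  stopifnot(inherits(an, "annotated_network"))
  anchors <- identify_anchors(an, fits)
  seeds <- spawn_seeds(cfg$seed, 2)
  if (length(anchors) == 0) {
    empty <- structure(list(modules = list(), min_anchors = min_anchors,
                            seed = cfg$seed), class = "module_set")
    return(structure(list(anchors = character(0), M = NULL,
                          clusters = list(), modules = empty),
                     class = "module_discovery"))
  }
  cfg_m <- sampling_config(n_iter = cfg$n_iter, k = cfg$k, mode = cfg$mode,
                           seed = seeds[1])
  M <- co_membership(an, fits, cfg_m, nodes = anchors)
  clusters <- cluster_anchors(M, cut = cut, cut_is_distance = cut_is_distance)
  modules <- build_modules(an$network, clusters, an,
                           min_anchors = min_anchors, seed = seeds[2])
  structure(list(anchors = anchors, M = M, clusters = clusters,
                 modules = modules),
            class = "module_discovery")
}

#' @export
print.module_discovery <- function(x, ...) {
  cat(sprintf("Module discovery: %d anchors, %d cluster(s)\n",
              length(x$anchors), length(x$clusters)))
  print(x$modules)
  invisible(x)
}
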