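#' Shuffle observed p-values within node types
#'
#' The topology-aware null: observed p-values are permuted among the same
#' observed node positions, EC values among observed EC nodes and metabolite
#' values among observed metabolite nodes. Unobserved nodes stay unobserved,
#' so per-type p-value multisets, coverage and the fitted mixture (hence
#' tau) are all invariant.
#'
#' @param an an annotated network.
#' @param seed optional integer seed.
#' @return a new \code{annotated_network} with shuffled p-values.
#' @export
shuffle_scores <- function(an, seed = NULL) {
  stopifnot(inherits(an, "annotated_network"))
  if (!is.null(seed)) {
    old <- local_seed(seed)
    on.exit(restore_seed(old), add = TRUE)
  }
  types <- node_types(an$network)
  p <- an$p
  for (ty in c("EC", "METABOLITE")) {
    ids <- an$observed[types[an$observed] == ty]
    if (length(ids) > 1) p[ids] <- sample(an$p[ids])
  }
  out <- an
  out$p <- p
  out
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment (monotone, capped at 1).
#'
#' @param pvalues numeric vector in (0, 1].
#' @return q-values in the input order.
#' @export
fdr_correct <- function(pvalues) {
  stats::p.adjust(pvalues, method = "BH")
}

#' Topology-aware permutation test for module significance
#'
#' Dense regions of the network can yield low-p modules by chance. For each
#' of \code{B} shuffles of the observed p-values (within node type), the full
#' identification procedure — anchors, co-membership, clustering, Steiner
#' completion, validity — is rerun with the same mixture fits (which are
#' invariant under within-type permutation). A shuffle is a success for a
#' real valid module with \code{N_EC} anchor ECs, \code{N_met} anchor
#' metabolites and mean anchor p-value \code{p_hat} when (a) the shuffle
#' yields at least as many valid modules as the real run and (b) some valid
#' shuffle module has \code{>= N_EC} anchor ECs, \code{>= N_met} anchor
#' metabolites and \code{<= p_hat} mean anchor p-value. The permutation
#' p-value is \code{(successes + 1) / (B + 1)}; q-values are
#' Benjamini-Hochberg across the valid modules. Invalid modules get
#' \code{p_perm = q = 1}.
#'
#' @param an the (unshuffled) annotated network.
#' @param fits per-type \code{bum_fit} list.
#' @param cfg \code{\link{sampling_config}} used for the shuffled reruns.
#' @param real_modules the real run's \code{module_set}
#'   (\code{\link{build_modules}}).
#' @param B number of shuffles (default 100).
#' @param cut clustering cut, as in the real run.
#' @param cut_is_distance see \code{\link{cluster_anchors}}.
#' @param seed master seed for the shuffle substreams.
#' @param n_iter_shuffle Monte-Carlo iterations per shuffled rerun; defaults
#'   to \code{cfg$n_iter}. A smaller value gives an approximate, faster test
#'   and is flagged in the result.
#' @param gate \code{"global"} (default): every tested module requires the
#'   shuffle to yield at least as many valid modules as the real run;
#'   \code{"rank"}: the module ranked r by mean anchor p-value requires only
#'   r valid shuffle modules.
#' @return a \code{module_set} equal to \code{real_modules} with
#'   \code{p_perm}, \code{q} and \code{significant} (q < 0.1) filled in; the
#'   per-module permutation counts are attached as attribute
#'   \code{"permutation"} (data frame: module_id, n_perm, n_success, p_perm,
#'   q).
#' @export
permutation_test <- function(an, fits, cfg, real_modules, B = 100,
                             cut = 0.8, cut_is_distance = TRUE, seed = 1L,
                             n_iter_shuffle = NULL,
                             gate = c("global", "rank")) {
  stopifnot(inherits(real_modules, "module_set"))
  gate <- match.arg(gate)
  if (B < 1) stop("B must be >= 1")
  if (length(real_modules$modules) == 0) stop("no real modules to test")
  n_iter_shuffle <- n_iter_shuffle %||% cfg$n_iter
  min_anchors <- real_modules$min_anchors

  real <- as.data.frame(real_modules)
  valid_idx <- which(real$valid)
  n_valid_real <- length(valid_idx)
  # rank of each valid module by ascending p_hat (modules are pre-sorted)
  rank_of <- seq_along(valid_idx)

  seeds <- spawn_seeds(seed, B)
  succ <- integer(n_valid_real)
  for (b in seq_len(B)) {
    sub <- spawn_seeds(seeds[b], 2)
    an_s <- shuffle_scores(an, seed = sub[1])
    cfg_s <- sampling_config(n_iter = n_iter_shuffle, k = cfg$k,
                             mode = cfg$mode, seed = sub[2])
    ds <- discover_modules(an_s, fits, cfg = cfg_s, cut = cut,
                           cut_is_distance = cut_is_distance,
                           min_anchors = min_anchors)
    sdf <- as.data.frame(ds$modules)
    sdf <- sdf[sdf$valid, , drop = FALSE]
    n_valid_s <- nrow(sdf)
    for (i in seq_len(n_valid_real)) {
      need <- if (gate == "global") n_valid_real else rank_of[i]
      if (n_valid_s < need) next
      ri <- real[valid_idx[i], ]
      dom <- sdf$n_ec_anchors >= ri$n_ec_anchors &
        sdf$n_met_anchors >= ri$n_met_anchors &
        sdf$p_hat <= ri$p_hat
      if (any(dom)) succ[i] <- succ[i] + 1
    }
  }

  p_perm <- rep(1, nrow(real))
  p_perm[valid_idx] <- (succ + 1) / (B + 1)
  q <- rep(1, nrow(real))
  q[valid_idx] <- fdr_correct(p_perm[valid_idx])

  out <- real_modules
  for (i in seq_along(out$modules)) {
    out$modules[[i]]$p_perm <- p_perm[i]
    out$modules[[i]]$q <- q[i]
    out$modules[[i]]$significant <- q[i] < 0.1
  }
  attr(out, "permutation") <- data.frame(
    module_id = real$module_id, n_perm = B,
    n_success = replace(rep(NA_integer_, nrow(real)), valid_idx, succ),
    p_perm = p_perm, q = q, stringsAsFactors = FALSE
  )
  attr(out, "approximate") <- n_iter_shuffle < cfg$n_iter
  out
}
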