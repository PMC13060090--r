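#' Sampling configuration for module discovery
#'
#' Bundles the tunable parameters of the Monte-Carlo co-membership stage.
#'
#' @param n_iter number of labelling iterations (default 1000).
#' @param k path-length bound: two nodes count as connected in an iteration
#'   when joined by a path of strictly fewer than \code{k} edges through
#'   DA-labelled nodes. Default 4: in a bipartite enzyme-metabolite graph,
#'   same-type distances are even and cross-type distances odd, so k = 4
#'   (paths of up to 3 edges) is the smallest bound that links both an
#'   EC pair sharing a metabolite and a non-adjacent EC-metabolite pair one
#'   reaction step apart.
#' @param mode labelling probability mode, see \code{\link{da_probability}}.
#' @param seed master seed; every iteration gets its own substream so
#'   results are independent of execution order.
#' @return an object of class \code{sampling_config}.
#' @export
sampling_config <- function(n_iter = 1000, k = 4,
                            mode = c("one_minus_p", "bum_posterior"),
                            seed = 1L) {
  stopifnot(n_iter >= 1, k >= 1)
  structure(
    list(n_iter = as.integer(n_iter), k = as.integer(k),
         mode = match.arg(mode), seed = as.integer(seed)),
    class = "sampling_config"
  )
}

#' Identify anchor nodes
#'
#' Anchors are the high-confidence seeds of module discovery: nodes that are
#' both observed and have a p-value strictly below the mixture-derived
#' threshold tau of their node type. A type whose fit carries the sentinel
#' \code{tau = 0} contributes no anchors.
#'
#' @param an an annotated network (\code{\link{project_scores}}).
#' @param fits per-type fits (\code{\link{fit_bum_per_type}}).
#' @return character vector of anchor node ids (sorted).
#' @export
identify_anchors <- function(an, fits) {
  stopifnot(inherits(an, "annotated_network"))
  types <- node_types(an$network)
  anchors <- character(0)
  for (ty in c("EC", "METABOLITE")) {
    fit <- fits[[ty]]
    if (is.null(fit) || fit$tau <= 0) next
    obs <- an$observed[types[an$observed] == ty]
    anchors <- c(anchors, obs[an$p[obs] < fit$tau])
  }
  sort(anchors)
}

# Internal: precompute the per-iteration sampling context (node order,
# adjacency, observed p-values, unobserved indices per type).
sampling_context <- function(an, fits, mode) {
  net <- an$network
  ids <- net$nodes$node_id
  n <- length(ids)
  types <- net$nodes$node_type
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  if (nrow(net$edges) > 0) {
    i <- match(net$edges$ec_id, ids)
    j <- match(net$edges$metabolite_id, ids)
    A[cbind(i, j)] <- 1
    A[cbind(j, i)] <- 1
  }
  p0 <- rep(NA_real_, n)
  p0[match(an$observed, ids)] <- an$p[an$observed]
  list(
    ids = ids, n = n, types = types, A = A, p0 = p0,
    unobs_ec = which(is.na(p0) & types == "EC"),
    unobs_met = which(is.na(p0) & types == "METABOLITE"),
    fits = fits, mode = mode
  )
}

# Internal: one labelling iteration under the current RNG state.
# Returns a logical DA vector over ctx$ids.
draw_da <- function(ctx) {
  p <- ctx$p0
  if (length(ctx$unobs_ec) > 0) {
    if (is.null(ctx$fits$EC)) stop("no EC fit available to impute EC nodes")
    p[ctx$unobs_ec] <- rbum(length(ctx$unobs_ec), ctx$fits$EC$a,
                            ctx$fits$EC$lam)
  }
  if (length(ctx$unobs_met) > 0) {
    if (is.null(ctx$fits$METABOLITE)) {
      stop("no metabolite fit available to impute metabolite nodes")
    }
    p[ctx$unobs_met] <- rbum(length(ctx$unobs_met), ctx$fits$METABOLITE$a,
                             ctx$fits$METABOLITE$lam)
  }
  prob <- numeric(ctx$n)
  for (ty in c("EC", "METABOLITE")) {
    sel <- ctx$types == ty
    if (!any(sel)) next
    prob[sel] <- da_probability(p[sel], ctx$fits[[ty]], ctx$mode)
  }
  stats::runif(ctx$n) < prob
}

#' Draw one disease-associated node set
#'
#' Runs a single Monte-Carlo labelling iteration: unobserved nodes receive a
#' p-value drawn from their type's fitted mixture, then every node is
#' independently labelled DA with probability \code{\link{da_probability}}.
#'
#' @param an an annotated network.
#' @param fits per-type \code{bum_fit} list.
#' @param cfg a \code{\link{sampling_config}} (its \code{mode} is used).
#' @param seed optional integer seed for this draw.
#' @return character vector of DA-labelled node ids.
#' @export
sample_da_set <- function(an, fits, cfg = sampling_config(), seed = NULL) {
  ctx <- sampling_context(an, fits, cfg$mode)
  if (!is.null(seed)) {
    old <- local_seed(seed)
    on.exit(restore_seed(old), add = TRUE)
  }
  ctx$ids[draw_da(ctx)]
}

#' Estimate the co-membership matrix M
#'
#' Runs \code{n_iter} labelling iterations. In each iteration the subgraph
#' induced by the DA-labelled nodes is considered, and a pair of nodes counts
#' as co-members when both are DA and connected by a path of strictly fewer
#' than \code{k} edges whose intermediate nodes are all DA. Entry
#' \code{M[u, v]} is the fraction of iterations in which u and v are
#' co-members; the diagonal is 1 for every node labelled DA at least once
#' (a node is trivially connected to itself).
#'
#' Reachability is computed by boolean propagation of the adjacency matrix
#' restricted to DA nodes, started from the rows of interest; this is
#' equivalent to a breadth-first search in the induced subgraph
#' (see \code{\link{bfs_reachable}}).
#'
#' @param an an annotated network.
#' @param fits per-type \code{bum_fit} list.
#' @param cfg a \code{\link{sampling_config}}.
#' @param nodes node ids to include as matrix rows/columns; default the
#'   anchors (\code{\link{identify_anchors}}). Use
#'   \code{nodes = an$network$nodes$node_id} for the full matrix.
#' @return an object of class \code{co_membership}: list with
#'   \code{node_ids}, \code{values} (symmetric matrix in [0,1]),
#'   \code{da_freq} (empirical DA frequency per node) and \code{n_iter}.
#' @export
co_membership <- function(an, fits, cfg = sampling_config(), nodes = NULL) {
  stopifnot(inherits(an, "annotated_network"))
  if (nrow(an$network$nodes) == 0) stop("empty network")
  if (is.null(nodes)) nodes <- identify_anchors(an, fits)
  nodes <- unique(nodes)
  ctx <- sampling_context(an, fits, cfg$mode)
  tgt <- match(nodes, ctx$ids)
  if (anyNA(tgt)) stop("nodes not in network: ",
                       paste(utils::head(nodes[is.na(tgt)], 5), collapse = ", "))
  m <- length(tgt)
  counts <- matrix(0, m, m, dimnames = list(nodes, nodes))
  da_count <- stats::setNames(numeric(m), nodes)
  seeds <- spawn_seeds(cfg$seed, cfg$n_iter)
  for (it in seq_len(cfg$n_iter)) {
    old <- local_seed(seeds[it])
    da <- draw_da(ctx)
    restore_seed(old)
    active <- which(da[tgt])          # positions within tgt
    da_count[active] <- da_count[active] + 1
    if (length(active) == 0) next
    reach <- reach_within(ctx$A, da, tgt[active], cfg$k)
    counts[active, ] <- counts[active, ] + reach[, tgt, drop = FALSE]
  }
  values <- counts / cfg$n_iter
  diag(values) <- as.numeric(da_count > 0)
  structure(
    list(node_ids = nodes, values = values, da_freq = da_count / cfg$n_iter,
         n_iter = cfg$n_iter, k = cfg$k, mode = cfg$mode, seed = cfg$seed),
    class = "co_membership"
  )
}

# Internal: boolean reachability by < k edges within the DA-induced
# subgraph, from the given source indices. Returns a 0/1 matrix
# length(sources) x n over all node columns.
reach_within <- function(A, da, sources, k) {
  n <- ncol(A)
  ns <- length(sources)
  reach <- matrix(0, ns, n)
  reach[cbind(seq_len(ns), sources)] <- 1   # distance 0 (sources are DA)
  if (k > 1) {
    cur <- reach
    da_num <- as.numeric(da)
    for (step in seq_len(k - 1)) {
      cur <- (cur %*% A > 0) * rep(da_num, each = ns)
      new <- cur > reach
      if (!any(new)) break
      reach[new] <- 1
    }
  }
  reach
}

#' @export
print.co_membership <- function(x, ...) {
  cat(sprintf("Co-membership matrix: %d nodes, %d iterations (k = %d, mode = %s)\n",
              length(x$node_ids), x$n_iter, x$k, x$mode))
  off <- x$values[upper.tri(x$values)]
  if (length(off) > 0) {
    cat(sprintf("  off-diagonal co-membership: min %.3f, median %.3f, max %.3f\n",
                min(off), stats::median(off), max(off)))
  }
  invisible(x)
}

#' @export
as.matrix.co_membership <- function(x, ...) x$values

#' Write a co-membership matrix as TSV
#'
#' @param M a \code{\link{co_membership}} object.
#' @param path output path (node ids as header row and first column).
#' @return \code{path}, invisibly.
#' @export
write_co_membership <- function(M, path) {
  df <- data.frame(node_id = M$node_ids, M$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
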