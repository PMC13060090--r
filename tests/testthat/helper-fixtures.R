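# Shared fixtures and independent oracles.

# small bipartite nets --------------------------------------------------------

toy_net <- function() {
  metabolic_network(data.frame(
    ec_id = c("E1", "E1", "E2"),
    metabolite_id = c("M1", "M2", "M2"),
    stringsAsFactors = FALSE
  ))
}

# alternating EC/metabolite path of n nodes: E1 - M1 - E2 - M2 - ...
path_net <- function(n) {
  ids <- character(n)
  ids[seq(1, n, by = 2)] <- paste0("E", seq_len(ceiling(n / 2)))
  if (n > 1) ids[seq(2, n, by = 2)] <- paste0("M", seq_len(floor(n / 2)))
  edges <- data.frame(a = ids[-n], b = ids[-1], stringsAsFactors = FALSE)
  ec_first <- startsWith(edges$a, "E")
  metabolic_network(data.frame(
    ec_id = ifelse(ec_first, edges$a, edges$b),
    metabolite_id = ifelse(ec_first, edges$b, edges$a),
    stringsAsFactors = FALSE
  ))
}

# annotated network from a named p-value vector (names = node ids)
annotate <- function(net, p) {
  types <- node_types(net)
  mk <- function(ty) {
    ids <- intersect(names(p), names(types)[types == ty])
    if (length(ids) == 0) return(NULL)
    score_table(ids, ty, unname(p[ids]))
  }
  project_scores(net, mk("EC"), mk("METABOLITE"))
}

# hand-built fit / co-membership objects for stage-level tests ----------------

fixed_fit <- function(a, lam, fdr_level = 0.1) {
  fit <- structure(
    list(a = a, lam = lam, tau = NA_real_, loglik = NA_real_, n = 0L,
         fdr_level = fdr_level, boundary = FALSE, degenerate = FALSE),
    class = "bum_fit"
  )
  fit$tau <- suppressWarnings(fdr_threshold(fit, fdr_level))
  fit
}

fixed_M <- function(values, n_iter = 1000L) {
  structure(
    list(node_ids = rownames(values), values = values,
         da_freq = stats::setNames(rep(1, nrow(values)), rownames(values)),
         n_iter = n_iter, k = 4L, mode = "one_minus_p", seed = 1L),
    class = "co_membership"
  )
}

# independent oracles ---------------------------------------------------------

# exhaustive grid search of the BUM log-likelihood
grid_bum_max <- function(p, n_grid = 200) {
  grid <- seq(1 / (2 * n_grid), 1 - 1 / (2 * n_grid), length.out = n_grid)
  best <- c(ll = -Inf, a = NA, lam = NA)
  for (a in grid) {
    t <- a * p^(a - 1)
    ll <- vapply(grid, function(lam) sum(log(lam + (1 - lam) * t)), 1)
    i <- which.max(ll)
    if (ll[i] > best["ll"]) best <- c(ll = ll[i], a = a, lam = grid[i])
  }
  best
}

# bisection root of the Pounds-Morris FDR identity
bisect_tau <- function(a, lam, fdr, tol = 1e-12) {
  pi_ub <- lam + (1 - lam) * a
  f <- function(t) pi_ub * t / (lam * t + (1 - lam) * t^a) - fdr
  lo <- 1e-300
  hi <- 1 - 1e-12
  if (f(hi) < 0) return(NA_real_)
  for (i in 1:2000) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

# exhaustive path enumeration: nodes reachable from source by simple paths of
# < max_len edges within the subgraph induced by `allowed`
brute_reachable <- function(net, allowed, source, max_len) {
  adj <- list()
  for (i in seq_len(nrow(net$edges))) {
    a <- net$edges$ec_id[i]
    b <- net$edges$metabolite_id[i]
    if (a %in% allowed && b %in% allowed) {
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  found <- source
  grow <- function(node, depth) {
    if (depth >= max_len - 1) return()
    for (nb in adj[[node]]) {
      if (!(nb %in% found)) found <<- c(found, nb)
      # re-descend regardless: shortest distances only shrink with depth
    }
  }
  frontier <- source
  depth <- 0
  while (length(frontier) > 0 && depth < max_len - 1) {
    nxt <- setdiff(unique(unlist(adj[frontier])), found)
    found <- c(found, nxt)
    frontier <- nxt
    depth <- depth + 1
  }
  sort(found)
}

# exact Steiner cost by subset enumeration: minimum |S| - 1 over connected
# node sets S containing the terminals
brute_steiner_cost <- function(net, terminals) {
  ids <- net$nodes$node_id
  others <- setdiff(ids, terminals)
  g <- as_igraph(net)
  connected <- function(S) {
    sub <- igraph::induced_subgraph(g, S)
    igraph::components(sub)$no == 1
  }
  for (extra in 0:length(others)) {
    if (extra == 0) {
      if (connected(terminals)) return(length(terminals) - 1)
      next
    }
    sets <- utils::combn(others, extra, simplify = FALSE)
    for (s in sets) {
      if (connected(c(terminals, s))) return(length(terminals) + extra - 1)
    }
  }
  stop("terminals not connectable")
}

# hypergeometric upper-tail by direct choose() summation
brute_hyper_upper <- function(x, K, n, N) {
  lo <- max(0, n + K - N)
  hi <- min(n, K)
  if (x > hi) return(0)
  i <- max(x, lo):hi
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

# Benjamini-Hochberg step-up from the definition
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  pmin(q, 1)[order(o)]
}

is_connected_nodes <- function(net, nodes) {
  if (length(nodes) <= 1) return(TRUE)
  sub <- igraph::induced_subgraph(as_igraph(net), nodes)
  igraph::components(sub)$no == 1
}

# pure-noise score tables at given coverages (for null-calibration studies)
uniform_scores <- function(net, coverage_ec, coverage_met, seed) {
  types <- node_types(net)
  ids <- net$nodes$node_id
  set.seed(seed)
  obs <- stats::runif(length(ids)) <
    ifelse(types[ids] == "EC", coverage_ec, coverage_met)
  p <- stats::runif(length(ids))
  mk <- function(ty) {
    sel <- obs & types[ids] == ty
    if (!any(sel)) return(NULL)
    score_table(ids[sel], ty, p[sel])
  }
  list(ec = mk("EC"), met = mk("METABOLITE"))
}
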