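test_that("anchor clustering separates blocks and isolates noise", {
  ids <- c("A", "B", "C", "D")
  V <- matrix(0, 4, 4, dimnames = list(ids, ids))
  V[1:2, 1:2] <- 1
  V[3:4, 3:4] <- 1
  cl <- cluster_anchors(fixed_M(V), cut = 0.8)
  expect_length(cl, 2)
  expect_equal(cl[[1]]$anchors, c("A", "B"))
  expect_equal(cl[[2]]$anchors, c("C", "D"))

  # no co-membership at all: every anchor its own flagged singleton
  Z <- diag(4)
  dimnames(Z) <- list(ids, ids)
  cl0 <- cluster_anchors(fixed_M(Z), cut = 0.8)
  expect_length(cl0, 4)
  expect_true(all(vapply(cl0, `[[`, TRUE, "singleton")))

  expect_equal(cluster_anchors(fixed_M(Z[0, 0, drop = FALSE])), list())
})

test_that("average linkage merges by mean co-membership (hand-worked case)", {
  ids <- c("A", "B", "C")
  V <- diag(3)
  dimnames(V) <- list(ids, ids)
  V["A", "B"] <- V["B", "A"] <- 0.9
  V["A", "C"] <- V["C", "A"] <- 0.9
  V["B", "C"] <- V["C", "B"] <- 0.85
  # merge A-B at distance 0.1; C joins at average (0.1 + 0.15) / 2 = 0.125
  for (dist_cut in c(TRUE, FALSE)) {
    cl <- cluster_anchors(fixed_M(V), cut = 0.8, cut_is_distance = dist_cut)
    expect_length(cl, 1)
    expect_equal(cl[[1]]$anchors, ids)
  }
  # similarity reading is stricter than the height reading
  V["A", "C"] <- V["C", "A"] <- 0.4
  V["B", "C"] <- V["C", "B"] <- 0.4
  # avg distance of C to {A,B} = 0.6: merged at height 0.8, not at 0.2
  expect_length(cluster_anchors(fixed_M(V), 0.8, cut_is_distance = TRUE), 1)
  expect_length(cluster_anchors(fixed_M(V), 0.8, cut_is_distance = FALSE), 2)
})

test_that("Steiner completion returns connected, anchor-complete modules", {
  p5 <- path_net(5)    # E1 - M1 - E2 - M2 - E3
  m <- steiner_complete(p5, c("E1", "M1"), seed = 1)
  expect_setequal(m$nodes, c("E1", "M1"))
  expect_equal(nrow(m$edges), 1)

  # anchors at the two ends of the path: the unique completion is the path
  m2 <- steiner_complete(p5, c("E1", "E3"), seed = 1)
  expect_setequal(m2$nodes, p5$nodes$node_id)
  expect_length(m2$tree_edges, 4)

  two <- metabolic_network(data.frame(ec_id = c("E1", "E2"),
                                      metabolite_id = c("M1", "M2")))
  expect_error(steiner_complete(two, c("E1", "E2")), "components")
})

test_that("Steiner heuristic is reproducible and near-optimal on random graphs", {
  set.seed(555)
  for (rep in 1:25) {
    net <- generate_network(6, 6, mean_met_degree = 1.8, seed = rep + 300)
    comp <- connected_components(net)[[1]]
    if (length(comp) < 4) next
    terms <- sample(comp, sample(2:min(4, length(comp)), 1))
    m <- steiner_complete(net, terms, seed = rep)
    expect_true(all(terms %in% m$nodes))
    expect_true(is_connected_nodes(net, m$nodes))
    expect_identical(m$nodes, steiner_complete(net, terms, seed = rep)$nodes)
    opt <- brute_steiner_cost(net, terms)
    expect_lte(length(m$tree_edges), 2 * opt)
  }
})

test_that("module assembly computes anchor stats, validity and ordering", {
  p5 <- path_net(5)
  an <- annotate(p5, c(E1 = 0.01, M1 = 0.02, E2 = 0.03, M2 = 0.5, E3 = 0.9))
  clusters <- list(
    structure(list(anchors = c("E1", "M1", "E2"), singleton = FALSE),
              class = "anchor_cluster"),
    structure(list(anchors = "E3", singleton = TRUE),
              class = "anchor_cluster")
  )
  ms <- build_modules(p5, clusters, an, min_anchors = 2, seed = 3)
  df <- as.data.frame(ms)
  expect_equal(nrow(df), 2)
  expect_equal(df$p_hat, sort(df$p_hat))          # ascending mean anchor p
  expect_equal(df$p_hat[1], mean(c(0.01, 0.02, 0.03)))
  expect_true(df$valid[1])
  expect_false(df$valid[2])                       # singleton below min_anchors
  expect_equal(df$n_ec_anchors[1], 2)
  expect_equal(df$n_met_anchors[1], 1)
})

test_that("clusters always partition the anchor set", {
  set.seed(21)
  for (rep in 1:10) {
    n <- sample(3:12, 1)
    ids <- paste0("A", seq_len(n))
    V <- matrix(runif(n * n), n, n, dimnames = list(ids, ids))
    V <- (V + t(V)) / 2
    diag(V) <- 1
    cl <- cluster_anchors(fixed_M(V), cut = 0.8)
    members <- unlist(lapply(cl, `[[`, "anchors"))
    expect_setequal(members, ids)
    expect_equal(anyDuplicated(members), 0)
  }
})

test_that("discovery output modules induce connected subgraphs", {
  net <- generate_network(40, 40, seed = 17)
  sim <- plant_signal(net, 8, 0.1, coverage_ec = 1, coverage_met = 1,
                      seed = 17)
  an <- project_scores(net, sim$ec_scores, sim$met_scores)
  fits <- suppressWarnings(fit_bum_per_type(an))
  d <- discover_modules(an, fits, sampling_config(n_iter = 150, seed = 17))
  for (m in d$modules$modules) {
    expect_true(is_connected_nodes(net, m$nodes))
    expect_true(all(m$anchors %in% m$nodes))
  }
  # bit-for-bit reproducibility of the whole stage
  d2 <- discover_modules(an, fits, sampling_config(n_iter = 150, seed = 17))
  expect_identical(lapply(d$modules$modules, `[[`, "nodes"),
                   lapply(d2$modules$modules, `[[`, "nodes"))
  expect_identical(d$M$values, d2$M$values)
})
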