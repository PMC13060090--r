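test_that("anchors are observed nodes strictly below their type's threshold", {
  net <- toy_net()
  fit_ec <- fixed_fit(0.2, 0.5)
  fit_met <- fixed_fit(0.2, 0.5)
  tau <- fit_ec$tau
  an <- annotate(net, c(E1 = tau / 2, E2 = tau, M1 = tau / 2))
  anchors <- identify_anchors(an, list(EC = fit_ec, METABOLITE = fit_met))
  expect_setequal(anchors, c("E1", "M1"))   # E2 at exactly tau is excluded
  # unobserved M2 can never be an anchor; sentinel tau yields no anchors
  expect_false("M2" %in% anchors)
  none <- list(EC = fixed_fit(0.2, 0.5), METABOLITE = fit_met)
  none$EC$tau <- 0
  expect_setequal(identify_anchors(an, none), "M1")
})

test_that("DA sets follow the labelling probabilities", {
  net <- toy_net()
  fits <- list(EC = fixed_fit(0.5, 0.5), METABOLITE = fixed_fit(0.5, 0.5))
  cfg <- sampling_config(mode = "one_minus_p")
  all_one <- annotate(net, c(E1 = 1, E2 = 1, M1 = 1, M2 = 1))
  expect_length(sample_da_set(all_one, fits, cfg, seed = 1), 0)
  all_tiny <- annotate(net, c(E1 = 1e-10, E2 = 1e-10, M1 = 1e-10, M2 = 1e-10))
  expect_setequal(sample_da_set(all_tiny, fits, cfg, seed = 1),
                  net$nodes$node_id)
  expect_identical(sample_da_set(all_tiny, fits, cfg, seed = 9),
                   sample_da_set(all_tiny, fits, cfg, seed = 9))
})

test_that("imputed single unobserved node is DA at the analytic frequency", {
  net <- toy_net()
  an <- annotate(net, c(E1 = 1, E2 = 1, M1 = 1))  # M2 unobserved
  unif <- fixed_fit(0.5, 1 - 1e-6)
  fits <- list(EC = unif, METABOLITE = unif)
  cfg <- sampling_config(mode = "one_minus_p")
  hits <- vapply(seq_len(5000), function(i) {
    "M2" %in% sample_da_set(an, fits, cfg, seed = i)
  }, TRUE)
  se <- sqrt(0.25 / 5000)                         # E[1 - p] = 0.5 under U(0,1)
  expect_lt(abs(mean(hits) - 0.5), 3 * se)
})

test_that("co-membership on a fully associated path reaches certainty", {
  p3 <- path_net(3)   # E1 - M1 - E2
  an <- annotate(p3, c(E1 = 1e-10, M1 = 1e-10, E2 = 1e-10))
  fits <- list(EC = fixed_fit(0.5, 0.5), METABOLITE = fixed_fit(0.5, 0.5))
  M <- co_membership(an, fits, sampling_config(n_iter = 200, k = 3, seed = 4),
                     nodes = p3$nodes$node_id)
  expect_equal(M$values["E1", "E2"], 1)           # distance 2 < k = 3
  expect_equal(unname(diag(M$values)), rep(1, 3))
})

test_that("cross-component co-membership is identically zero", {
  two <- metabolic_network(data.frame(ec_id = c("E1", "E2"),
                                      metabolite_id = c("M1", "M2")))
  an <- annotate(two, c(E1 = 1e-10, M1 = 1e-10, E2 = 1e-10, M2 = 1e-10))
  fits <- list(EC = fixed_fit(0.5, 0.5), METABOLITE = fixed_fit(0.5, 0.5))
  M <- co_membership(an, fits, sampling_config(n_iter = 300, seed = 5),
                     nodes = two$nodes$node_id)
  expect_equal(M$values["E1", "E2"], 0)
  expect_equal(M$values["E1", "M2"], 0)
  expect_equal(M$values["M1", "M2"], 0)
})

test_that("single-edge co-membership matches the independence expectation", {
  one <- metabolic_network(data.frame(ec_id = "E1", metabolite_id = "M1"))
  an <- annotate(one, c(E1 = 0.5, M1 = 0.5))      # DA probability 0.5 each
  fits <- list(EC = NULL, METABOLITE = NULL)
  M <- co_membership(an, fits,
                     sampling_config(n_iter = 2000, k = 2,
                                     mode = "one_minus_p", seed = 6),
                     nodes = c("E1", "M1"))
  se <- sqrt(0.25 * 0.75 / 2000)
  expect_lt(abs(M$values["E1", "M1"] - 0.25), 3 * se)
})

test_that("co-membership invariants hold on random annotated networks", {
  set.seed(77)
  net <- generate_network(15, 15, seed = 3)
  ids <- net$nodes$node_id
  p <- setNames(runif(length(ids))^2, ids)
  an <- annotate(net, p[sample(ids, 20)])
  fits <- list(EC = fixed_fit(0.4, 0.7), METABOLITE = fixed_fit(0.4, 0.7))
  mk <- function(k) co_membership(an, fits,
                                  sampling_config(n_iter = 150, k = k,
                                                  seed = 13), nodes = ids)
  M2 <- mk(2); M4 <- mk(4)
  off <- upper.tri(M2$values)
  # pair bound: connection requires both endpoints DA
  bound <- outer(M2$da_freq, M2$da_freq, pmin)
  expect_true(all(M2$values[off] <= bound[off] + 1e-12))
  # monotone in k under the same per-iteration seeds
  expect_true(all(M4$values[off] >= M2$values[off] - 1e-12))
  # symmetry and range
  expect_equal(M4$values, t(M4$values))
  expect_true(all(M4$values >= 0 & M4$values <= 1))
  # diagonal is 1 exactly for nodes ever labelled DA
  expect_equal(unname(diag(M4$values)), as.numeric(M4$da_freq > 0))
})

test_that("matrix propagation equals BFS reachability on the DA subgraph", {
  set.seed(99)
  for (rep in 1:10) {
    net <- generate_network(6, 6, mean_met_degree = 1.5, seed = rep)
    ids <- net$nodes$node_id
    da <- setNames(runif(length(ids)) < 0.6, ids)
    if (!any(da)) next
    k <- sample(2:4, 1)
    A <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    i <- match(net$edges$ec_id, ids); j <- match(net$edges$metabolite_id, ids)
    A[cbind(i, j)] <- 1; A[cbind(j, i)] <- 1
    src <- which(da)
    reach <- metabodule:::reach_within(A, da, src, k)
    for (s in seq_along(src)) {
      got <- sort(ids[reach[s, ] == 1])
      want <- bfs_reachable(net, ids[da], ids[src[s]], k)
      expect_equal(got, want, info = sprintf("rep %d src %s k %d",
                                             rep, ids[src[s]], k))
    }
  }
})
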