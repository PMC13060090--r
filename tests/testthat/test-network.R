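test_that("edge lists are read with node/edge deduplication and validation", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("ec_id\tmetabolite_id", "E1\tM1", "E1\tM2", "E2\tM2"), f)
  net <- read_edge_list(f)
  expect_equal(sum(net$nodes$node_type == "EC"), 2)
  expect_equal(sum(net$nodes$node_type == "METABOLITE"), 2)
  expect_equal(nrow(net$edges), 3)

  writeLines(c("ec_id\tmetabolite_id", "E1\tM1", "E1\tM1"), f)
  expect_equal(nrow(read_edge_list(f)$edges), 1)

  writeLines(c("ec_id\tmetabolite_id", "E1\tM1", "E2\tE1"), f)
  expect_error(read_edge_list(f), "both EC and metabolite")

  writeLines(c("ec_id\tmetabolite_id", "E1\tM1", "E2"), f)
  expect_error(read_edge_list(f), "line 3")

  expect_error(read_edge_list(tempfile()), "not found")
})

test_that("edge list writing round-trips", {
  net <- toy_net()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(net, f)
  back <- read_edge_list(f)
  expect_equal(back$nodes[order(back$nodes$node_id), ],
               net$nodes[order(net$nodes$node_id), ],
               ignore_attr = TRUE)
  expect_setequal(paste(back$edges$ec_id, back$edges$metabolite_id),
                  paste(net$edges$ec_id, net$edges$metabolite_id))
})

test_that("currency-metabolite filtering removes hubs but never ECs", {
  # star metabolite M1 touching 5 ECs plus a low-degree M2
  star <- metabolic_network(data.frame(
    ec_id = c(paste0("E", 1:5), "E1"),
    metabolite_id = c(rep("M1", 5), "M2")
  ))
  out <- filter_currency_metabolites(star, max_degree = 4)
  expect_false("M1" %in% out$nodes$node_id)
  expect_equal(nrow(out$edges), 1)
  expect_equal(sum(out$nodes$node_type == "EC"), 5)   # isolated ECs retained
  expect_setequal(attr(out, "isolated_ec"), paste0("E", 2:5))

  # cutoff at the maximum degree leaves the network unchanged
  same <- filter_currency_metabolites(star, max_degree = 5)
  expect_equal(nrow(same$edges), nrow(star$edges))
  expect_setequal(same$nodes$node_id, star$nodes$node_id)

  out2 <- filter_currency_metabolites(toy_net(), explicit_list = "M2")
  expect_false("M2" %in% out2$nodes$node_id)
  expect_equal(nrow(out2$edges), 1)

  expect_error(filter_currency_metabolites(toy_net(), explicit_list = "E1"),
               "EC id")
  expect_error(filter_currency_metabolites(toy_net()), "exactly one")
  expect_error(filter_currency_metabolites(toy_net(), max_degree = 2,
                                           explicit_list = "M1"),
               "exactly one")
})

test_that("connected components partition the node set, sorted by size", {
  two <- metabolic_network(data.frame(ec_id = c("E1", "E2"),
                                      metabolite_id = c("M1", "M2")))
  cc <- connected_components(two)
  expect_length(cc, 2)
  expect_equal(lengths(cc), c(2, 2))
  expect_equal(cc[[1]], c("E1", "M1"))   # tie broken by smallest member

  empty <- metabolic_network(data.frame(ec_id = character(0),
                                        metabolite_id = character(0)))
  expect_equal(connected_components(empty), list())

  p3 <- path_net(3)
  expect_length(connected_components(p3), 1)
  expect_length(connected_components(p3)[[1]], 3)

  for (seed in 1:5) {
    net <- generate_network(12, 12, seed = seed)
    cc <- connected_components(net)
    expect_equal(sum(lengths(cc)), nrow(net$nodes))
    expect_setequal(unlist(cc), net$nodes$node_id)
    expect_true(all(diff(lengths(cc)) <= 0))
  }
})

test_that("bfs_reachable respects the strict path-length bound and induction", {
  p3 <- path_net(3)  # E1 - M1 - E2
  expect_equal(bfs_reachable(p3, c("E1", "M1", "E2"), "E1", 2),
               c("E1", "M1"))
  expect_equal(bfs_reachable(p3, c("E1", "M1", "E2"), "E1", 3),
               c("E1", "E2", "M1"))
  expect_equal(bfs_reachable(p3, c("E1", "E2"), "E1", 10), "E1")
  expect_error(bfs_reachable(p3, c("M1", "E2"), "E1", 2), "source")
})

test_that("bfs_reachable agrees with exhaustive enumeration on small graphs", {
  set.seed(11)
  for (rep in 1:20) {
    net <- generate_network(4, 4, mean_met_degree = 1.5, seed = rep)
    ids <- net$nodes$node_id
    allowed <- sample(ids, sample(2:length(ids), 1))
    src <- sample(allowed, 1)
    k <- sample(1:5, 1)
    expect_equal(bfs_reachable(net, allowed, src, k),
                 brute_reachable(net, allowed, src, k),
                 info = sprintf("rep %d, k %d", rep, k))
  }
})
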