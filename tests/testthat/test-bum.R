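test_that("mixture density and CDF are consistent and normalized", {
  for (par in list(c(0.2, 0.3), c(0.5, 0.5), c(0.9, 0.8))) {
    expect_equal(pbum(1, par[1], par[2]), 1)
    # CDF derivative matches density at interior points
    x <- c(0.1, 0.4, 0.7)
    h <- 1e-7
    expect_equal((pbum(x + h, par[1], par[2]) - pbum(x - h, par[1], par[2])) /
                   (2 * h),
                 dbum(x, par[1], par[2]), tolerance = 1e-5)
  }
})

test_that("maximum-likelihood fit recovers mixture parameters", {
  set.seed(101)
  p <- rbum(5000, a = 0.3, lam = 0.6)
  fit <- fit_bum(p)
  expect_lt(abs(fit$a - 0.3), 0.1)
  expect_lt(abs(fit$lam - 0.6), 0.1)
  # optimum at least as good as a coarse grid search
  g <- grid_bum_max(p, n_grid = 60)
  expect_gte(fit$loglik, g["ll"] - 1e-6)
})

test_that("uniform p-values are identified as noise", {
  set.seed(202)
  p <- runif(10000)
  fit <- suppressWarnings(fit_bum(p))
  # (a, lam) is not identifiable on the null ridge (a -> 1 is itself
  # uniform); the identifiable noise bound must be near 1 and the anchor
  # threshold must exclude essentially everything
  expect_gte(fit$pi_ub, 0.9)
  expect_lt(fit$tau, 1e-4)
  expect_equal(sum(p < fit$tau), 0)
})

test_that("fit input validation and degenerate cases behave", {
  expect_error(fit_bum(runif(10)), "at least 20")
  expect_warning(fit_bum(rep(0.5, 100)), "identical")
  fit <- suppressWarnings(fit_bum(rep(0.5, 100)))
  expect_gt(fit$lam, 0.99)
  expect_message(fit_bum(c(0, runif(99))), "clamped")
  expect_error(fit_bum(c(1.5, runif(99))), "0, 1")
})

test_that("FDR threshold closed form equals the numeric root and is monotone", {
  fit <- fixed_fit(0.3, 0.6)
  expect_lt(abs(fit$tau - bisect_tau(0.3, 0.6, 0.1)), 1e-9)
  expect_gt(fdr_threshold(fit, 0.2), fdr_threshold(fit, 0.1))
  # pure-noise limit: threshold collapses to the no-anchor sentinel
  noise <- structure(list(a = 0.999999, lam = 1 - 1e-9), class = "bum_fit")
  expect_warning(tau0 <- fdr_threshold(noise, 0.1), "sentinel")
  expect_identical(tau0, 0)
})

test_that("mixture sampling matches the analytic CDF", {
  fit <- fixed_fit(0.5, 0.5)
  expect_length(sample_pvalues(fit, 0), 0)
  x <- sample_pvalues(fit, 50000, seed = 7)
  f025 <- 0.5 * 0.25 + 0.5 * sqrt(0.25)       # lam*x + (1-lam)*x^a
  se <- sqrt(f025 * (1 - f025) / 50000)
  expect_lt(abs(mean(x <= 0.25) - f025), 3 * se)
  # boundary lam ~ 1: indistinguishable from uniform
  unif_fit <- fixed_fit(0.5, 1 - 1e-6)
  y <- sample_pvalues(unif_fit, 10000, seed = 8)
  expect_gt(stats::ks.test(y, "punif")$p.value, 0.01)
  # reproducible under the same seed
  expect_identical(sample_pvalues(fit, 100, seed = 3),
                   sample_pvalues(fit, 100, seed = 3))
})

test_that("DA labelling probability follows both modes and is monotone", {
  expect_equal(da_probability(1, mode = "one_minus_p"), 0)
  fit <- fixed_fit(0.5, 0.5)
  expect_equal(da_probability(0.5, fit, "bum_posterior"), 0.41421,
               tolerance = 1e-4)
  expect_gt(da_probability(1e-12, fit, "bum_posterior"), 0.999)
  set.seed(33)
  for (i in 1:10) {
    fit <- fixed_fit(runif(1, 0.05, 0.95), runif(1, 0.05, 0.95))
    p <- sort(runif(50))
    for (mode in c("one_minus_p", "bum_posterior")) {
      expect_true(all(diff(da_probability(p, fit, mode)) <= 1e-12),
                  info = paste(mode, i))
    }
  }
})

test_that("fitted-model methods expose the usual interface", {
  set.seed(5)
  p <- rbum(2000, 0.3, 0.5)
  fit <- fit_bum(p)
  expect_named(coef(fit), c("a", "lam"))
  expect_s3_class(logLik(fit), "logLik")
  expect_equal(as.numeric(logLik(fit)), fit$loglik)
  expect_length(simulate(fit, 10, seed = 1), 10)
  expect_equal(predict(fit, 0.2, type = "density"),
               dbum(0.2, fit$a, fit$lam))
  expect_equal(predict(fit, 0.2, type = "cdf"), pbum(0.2, fit$a, fit$lam))
  expect_equal(predict(fit, 0.2), da_probability(0.2, fit, "bum_posterior"))
  expect_output(print(fit), "Beta-uniform")
})

test_that("per-type fitting is independent and falls back on sparse omics", {
  net <- generate_network(60, 60, seed = 2)
  types <- node_types(net)
  ids <- net$nodes$node_id
  set.seed(12)
  p <- setNames(runif(length(ids)), ids)
  # only 5 observed metabolites: too few for a stable fit
  met_ids <- sample(ids[types[ids] == "METABOLITE"], 5)
  an <- annotate(net, p[c(ids[types[ids] == "EC"], met_ids)])
  expect_warning(fits <- fit_bum_per_type(an), "pure-noise")
  expect_identical(fits$METABOLITE$tau, 0)
  expect_s3_class(fits$EC, "bum_fit")
  expect_gt(fits$EC$n, 0)
})
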