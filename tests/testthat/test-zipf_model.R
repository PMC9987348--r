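test_that("ZM pmf matches closed forms, normalizes, and decreases", {
  expect_equal(zm_pmf(2, 0, 3), c(1, 1 / 4, 1 / 9) / sum(c(1, 1 / 4, 1 / 9)),
               tolerance = 1e-12)
  expect_equal(round(zm_pmf(2, 0, 3), 4), c(0.7347, 0.1837, 0.0816))
  expect_identical(zm_pmf(1.3, 7, 1), 1)
  expect_equal(zm_pmf(1, 1, 2), c(0.6, 0.4), tolerance = 1e-12)
  for (par in list(c(1.1, 0), c(1.57, 19.48), c(0.8, 100))) {
    p <- zm_pmf(par[1], par[2], 1e6)
    expect_lt(abs(sum(p) - 1), 1e-12)
    expect_true(all(diff(p) < 0))
  }
  expect_error(zm_pmf(-1, 0, 10), "alpha")
  expect_error(zm_pmf(1, -2, 10), "beta")
})

test_that("raising alpha steepens the distribution", {
  p1 <- zm_pmf(1.2, 5, 1000)
  p2 <- zm_pmf(1.8, 5, 1000)
  expect_gt(p2[1], p1[1])
  expect_lt(sum(p2[500:1000]), sum(p1[500:1000]))
})

test_that("log-likelihood matches hand computation", {
  expect_equal(zm_loglik(c(3, 1), 1, 0), 3 * log(2 / 3) + log(1 / 3),
               tolerance = 1e-12)
  expect_equal(round(zm_loglik(c(3, 1), 1, 0), 4), -2.3150)
  expect_identical(zm_loglik(1, 2, 0.5), 0)
})

test_that("the MLE matches an exhaustive grid search", {
  # optimizer and oracle search the same region; geometric-like decays
  # otherwise push the ZM likelihood along the alpha, beta -> Inf ridge
  box_a <- c(0.5, 3); box_b <- c(0, 5)
  counts <- c(100, 50, 25, 12, 6)
  oracle <- grid_oracle(counts)
  fit <- fit_zm(counts, alpha_bounds = box_a, beta_bounds = box_b)
  expect_lte(abs(fit$alpha - oracle["alpha"]), 0.01)
  expect_lte(abs(fit$beta - oracle["beta"]), 0.05)
  expect_gte(zm_loglik(counts, fit$alpha, fit$beta),
             zm_loglik(counts, oracle["alpha"], oracle["beta"]) - 1e-6)
  # random small instances (N <= 50)
  set.seed(42)
  for (i in 1:4) {
    n <- sample(5:50, 1)
    f <- sort(rpois(n, lambda = 30) + 1, decreasing = TRUE)
    o <- grid_oracle(f)
    ft <- fit_zm(f, alpha_bounds = box_a, beta_bounds = box_b)
    expect_gte(zm_loglik(f, ft$alpha, ft$beta),
               zm_loglik(f, o["alpha"], o["beta"]) - 1e-6)
    if (o["alpha"] > 0.51 && o["alpha"] < 2.99 && o["beta"] > 0.05 &&
        o["beta"] < 4.95) {
      expect_lte(abs(ft$alpha - o["alpha"]), 2 * 0.01)
      expect_lte(abs(ft$beta - o["beta"]), 2 * 0.05)
    }
  }
})

test_that("fitting counts exactly proportional to a ZM pmf recovers it", {
  f <- round(zm_pmf(1.4, 10, 1000) * 1e7)
  fit <- fit_zm(f)
  expect_lt(abs(fit$alpha - 1.4), 0.01)
  expect_lt(abs(fit$beta - 10), 0.3)
})

test_that("fitted parameters are invariant to the tie-break seed", {
  spec <- synthetic_spec(1.3, 5, 400, 30000, seed = 9)
  tab <- build_table(sample_zm(spec))
  fits <- lapply(c(0, 1, 99), function(s) fit_zm(assign_ranks(tab, s)))
  expect_identical(fits[[1]]$alpha, fits[[2]]$alpha)
  expect_identical(fits[[1]]$alpha, fits[[3]]$alpha)
  expect_identical(fits[[1]]$beta, fits[[3]]$beta)
})

test_that("beta = 0 data reduce to classic Zipf with beta-hat near 0", {
  fit <- fit_synthetic(1.3, 0, 2000, 300000, seed = 5)
  expect_lt(abs(fit$alpha - 1.3), 0.05)
  expect_lt(fit$beta, 0.5)
})

test_that("expected frequencies scale the pmf to the token total", {
  e <- expected_frequencies(1, 0, 2, 10)
  expect_equal(e, c(20 / 3, 10 / 3), tolerance = 1e-9)
  e2 <- expected_frequencies(1.57, 19.48, 5000, 123456)
  expect_lt(abs(sum(e2) - 123456), 1e-6)
})

test_that("fit evaluation correlates observed with expected frequencies", {
  f <- round(zm_pmf(1.5, 2, 100) * 1e5)
  ev <- evaluate_fit(f, 1.5, 2)
  expect_false(ev$degenerate)
  expect_gt(ev$pearson_linear, 0.9999)
  expect_gt(ev$pearson_loglog, 0.999)
  expect_true(ev$pearson_linear <= 1 && ev$pearson_linear >= -1)
  # increasing (non-rank-ordered) inputs are rejected
  expect_error(evaluate_fit(c(1, 2, 3), 1.5, 2), "non-increasing")
})

test_that("extreme preposition-scale parameters are flagged degenerate", {
  # French- and Spanish-preposition-scale fits
  expect_true(zm_degenerate(115.07, 476.04, 46))
  expect_true(zm_degenerate(129.8, 235.1, 17))
  # ordinary and even steep-but-representable fits are not
  expect_false(zm_degenerate(8.59, 33.97, 74))
  expect_false(zm_degenerate(49.77, 265.13, 38))
  for (a in c(0.5, 1, 1.57, 2)) expect_false(zm_degenerate(a, 19.48, 100))
  ev <- evaluate_fit(sort(rpois(46, 20) + 1, decreasing = TRUE), 115.07, 476.04)
  expect_true(ev$degenerate)
  expect_true(is.na(ev$pearson_linear) && is.na(ev$pearson_loglog))
})

test_that("split-half estimates track full-corpus estimates", {
  # two identical interleaved copies: halves are exchangeable with the corpus
  spec <- synthetic_spec(1.45, 8, 1500, 80000, seed = 21)
  stream <- sample_zm(spec)
  doubled <- rep(stream, each = 2)
  full <- fit_zm(assign_ranks(build_table(doubled)))
  sh <- split_half_fit(doubled, seed = 3)
  expect_identical(sh$method, "split_half")
  expect_lt(abs(sh$alpha - full$alpha), 0.05)
  # seed changes move the estimate only within sampling noise
  alphas <- vapply(1:4, function(s) split_half_fit(stream, seed = s)$alpha,
                   numeric(1))
  expect_lt(max(alphas) - min(alphas), 0.05)
  expect_error(split_half_fit(c("a", "b"), seed = 1))
})

test_that("discrete power-law fitting recovers exponents and thresholds", {
  vals <- draw_discrete_powerlaw(1.95, 50000, seed = 4)
  cf <- fit_clauset(vals)
  expect_lt(abs(cf$exponent - 1.95), 0.1)
  expect_true(cf$ks_distance >= 0 && cf$ks_distance <= 1)
  # an exact power-law multiset: tiny KS at a threshold at/near the minimum
  exact <- rep(1:200, times = round(30000 * (1:200)^(-2.2)))
  cf2 <- fit_clauset(exact)
  expect_lte(cf2$x_min, 3)
  expect_lt(cf2$ks_distance, 0.01)
  expect_error(fit_clauset(rep(3, 50)), "degenerate")
  expect_error(fit_clauset(1:5), "at least 10")
})

test_that("exponential-tailed data fit a power law worse than power-law data", {
  set.seed(8)
  geo <- rgeom(5000, prob = 0.05) + 1
  pl <- draw_discrete_powerlaw(1.95, 5000, seed = 8)
  # compare at a fixed threshold so the comparison is like for like
  d_of <- function(v) fit_clauset(v, max_candidates = 1L)$ks_distance
  expect_gt(d_of(geo), d_of(pl))
})
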