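# Transcript stub with a given age and token stream.
aged_transcript <- function(age, tokens, path) {
  list(meta = list(path = path, corpus_name = "dev", child_age_months = age,
                   ordering_key = path),
       tokens = tokens)
}

test_that("six-month bins tile the age axis and absorb each transcript once", {
  set.seed(5)
  co <- list(aged_transcript(11L, sample(letters, 50, TRUE), "a"),
             aged_transcript(0L, sample(letters, 40, TRUE), "b"),
             aged_transcript(24L, sample(letters, 30, TRUE), "c"),
             aged_transcript(NA_integer_, sample(letters, 25, TRUE), "d"))
  bins <- bin_by_age(co)
  expect_identical(vapply(bins, `[[`, character(1), "label"),
                   c("0;0–0;5", "0;6–0;11", "2;0–2;5"))
  expect_identical(vapply(bins, `[[`, integer(1), "n_tokens"),
                   c(40L, 50L, 30L))
  # aged tokens across bins + unaged tokens = corpus total
  expect_identical(sum(vapply(bins, `[[`, integer(1), "n_tokens")) +
                     attr(bins, "unaged_tokens"), 145L)
  # bin boundaries: month 6 belongs to 0;6-0;11, month 5 to 0;0-0;5
  b2 <- bin_by_age(list(aged_transcript(6L, "x", "p"),
                        aged_transcript(5L, "y", "q")))
  expect_identical(vapply(b2, `[[`, character(1), "label"),
                   c("0;0–0;5", "0;6–0;11"))
})

test_that("bins below the token floor are summarized but not fitted", {
  spec_big <- synthetic_spec(1.4, 8, 800, 6000, seed = 31)
  spec_small <- synthetic_spec(1.4, 8, 300, 800, seed = 32)
  co <- list(aged_transcript(7L, sample_zm(spec_small), "small"),
             aged_transcript(25L, sample_zm(spec_big), "big"))
  df <- fit_bins(bin_by_age(co), min_tokens = 5000)
  expect_identical(df$fitted, c(FALSE, TRUE))
  expect_true(is.na(df$alpha[1]) && is.na(df$pearson_r[1]))
  expect_false(is.na(df$alpha[2]))
  expect_identical(df$n_tokens[1], 800L)  # summarized, with counts reported
  # the floor is inclusive
  df2 <- fit_bins(bin_by_age(co), min_tokens = 800)
  expect_true(all(df2$fitted))
  # raising the floor never adds fitted bins
  for (floor_k in c(500, 900, 7000)) {
    expect_lte(sum(fit_bins(bin_by_age(co), min_tokens = floor_k)$fitted),
               sum(fit_bins(bin_by_age(co), min_tokens = 500)$fitted))
  }
})

# Synthetic per-bin fit tables at the scale of the developmental analysis:
# 5 languages x 6 bins, a language-level intercept, and an injected slope.
simulate_bin_fits <- function(slope, seed, resid_sd = 0.01) {
  set.seed(seed)
  langs <- paste0("L", 1:5)
  ages <- seq(6, 36, by = 6)
  do.call(rbind, lapply(langs, function(l) {
    base <- 1.4 + rnorm(1, 0, 0.05)
    data.frame(language = l, start_months = ages,
               alpha = base + slope * (ages - mean(ages)) +
                 rnorm(length(ages), 0, resid_sd),
               pearson_r = 0.97 + rnorm(length(ages), 0, 0.005))
  }))
}

test_that("age trends recover an injected slope and report flat data as flat", {
  d <- simulate_bin_fits(slope = -0.002, seed = 14)
  tr <- age_trend(d, response = "alpha")
  expect_lt(abs(tr$slope - (-0.002)), 2 * tr$std_error)
  expect_true(tr$p_value >= 0 && tr$p_value <= 1)
  # constant response: slope exactly 0
  d0 <- simulate_bin_fits(slope = 0, seed = 15)
  d0$alpha <- 1.5
  # lm warns about a perfect fit on exactly constant data; that is the point
  tr0 <- suppressWarnings(age_trend(d0, response = "alpha"))
  expect_equal(tr0$slope, 0, tolerance = 1e-10)
  expect_error(age_trend(d[d$language == "L1", ], response = "alpha"),
               "2 languages")
})

test_that("null age trends yield roughly uniform p-values", {
  ps <- vapply(1:40, function(i) {
    age_trend(simulate_bin_fits(slope = 0, seed = 400 + i),
              response = "alpha")$p_value
  }, numeric(1))
  expect_gt(mean(ps), 0.25)
  expect_lt(mean(ps), 0.75)
  expect_lte(mean(ps < 0.05), 0.2)
})
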