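test_that("ZM sampling is seeded, deterministic, and calibrated", {
  spec <- synthetic_spec(1.4, 10, 500, 20000, seed = 17)
  s1 <- sample_zm(spec)
  s2 <- sample_zm(spec)
  expect_identical(s1, s2)
  expect_length(s1, 20000)
  # single-type vocabulary
  one <- sample_zm(synthetic_spec(1.2, 0, 1, 50, seed = 1))
  expect_identical(unique(one), "w1")
  # empirical top-word share within 3 binomial SEs of p(1)
  p1 <- zm_pmf(1.4, 10, 500)[1]
  share <- mean(s1 == "w001")
  expect_lt(abs(share - p1), 3 * sqrt(p1 * (1 - p1) / 20000))
  # sampling does not disturb the caller's RNG stream
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(sample_zm(spec)); after <- runif(1)
  expect_identical(before, after)
})

test_that("uniform baseline streams are exactly balanced", {
  u <- uniform_corpus(4, 8, seed = 1)
  expect_identical(as.integer(table(u)), rep(2L, 4))
  u2 <- uniform_corpus(7, 23, seed = 2)
  expect_identical(sort(as.integer(table(u2)), decreasing = TRUE),
                   c(4L, 4L, 3L, 3L, 3L, 3L, 3L))
  expect_identical(length(unique(u2)), 7L)  # type/token ratio exact
  expect_error(uniform_corpus(10, 5), "exceed")
})

test_that("written corpora round-trip through parsing exactly", {
  spec <- synthetic_spec(1.45, 6, 400, 15000, seed = 23,
                         age_schedule = c(3L, 11L, 24L),
                         child_fraction = 0.15)
  d <- file.path(tempdir(), "zipfcds-rt")
  on.exit(unlink(d, recursive = TRUE))
  make_corpus(spec, d)
  tc <- token_corpus(read_chat_corpus(d))
  got <- unlist(lapply(tc, `[[`, "tokens"), use.names = FALSE)
  want <- sample_zm(spec)
  expect_identical(length(got), 15000L)
  expect_identical(c(table(got)), c(table(want)))  # exact multiset
  # age schedule lands in the expected developmental bins
  bins <- bin_by_age(tc)
  expect_identical(vapply(bins, `[[`, character(1), "label"),
                   c("0;0–0;5", "0;6–0;11", "2;0–2;5"))
  # child_fraction = 0 means no child tiers at all
  spec0 <- synthetic_spec(1.45, 6, 300, 4000, seed = 2, child_fraction = 0)
  d0 <- file.path(tempdir(), "zipfcds-rt0")
  on.exit(unlink(d0, recursive = TRUE), add = TRUE)
  make_corpus(spec0, d0)
  ts0 <- read_chat_corpus(d0)
  expect_identical(length(unlist(lapply(token_corpus(ts0), `[[`, "tokens"))),
                   4000L)
  expect_false(any(unlist(lapply(ts0, function(t) t$utterances$speaker)) ==
                     "CHI"))
})

test_that("POS-profiled corpora carry recoverable tags", {
  prof <- list(noun = list(alpha = 1.3, beta = 5, vocab = 150, share = 0.5,
                           tag = "n"),
               verb = list(alpha = 1.6, beta = 8, vocab = 80, share = 0.3,
                           tag = "v"),
               adjective = list(alpha = 1.5, beta = 3, vocab = 60,
                                share = 0.15, tag = "adj"),
               preposition = list(alpha = 3, beta = 1, vocab = 12,
                                  share = 0.05, tag = "prep"))
  spec <- synthetic_spec(1.4, 10, 500, 8000, seed = 12, pos_profile = prof)
  d <- file.path(tempdir(), "zipfcds-pos")
  on.exit(unlink(d, recursive = TRUE))
  make_corpus(spec, d)
  utts <- lapply(read_chat_corpus(d), filter_adult)
  per_cat <- lapply(c(n = "n", v = "v", adj = "adj", prep = "prep"),
                    function(tag) extract_pos_tokens(utts, tag))
  expect_identical(sum(lengths(per_cat)), 8000L)
  # word-form prefixes encode the generating category exactly
  for (tag in names(per_cat)) {
    expect_true(all(startsWith(per_cat[[tag]], paste0(tag, "_"))))
  }
})

test_that("recovery experiments report estimates, bias and RMSE", {
  rep0 <- recovery_experiment(1.4, 5, 10000, replicates = 0, seed = 1)
  expect_identical(nrow(rep0), 0L)
  rec <- recovery_experiment(c(1.2, 1.6), 5, 30000, vocab_size = 800,
                             replicates = 2, seed = 3)
  expect_identical(nrow(rec), 4L)
  expect_true(all(is.na(rec$error)))
  sm <- attr(rec, "summary")
  expect_identical(nrow(sm), 2L)
  expect_true(all(abs(sm$bias_alpha) < 0.1))
  # small samples estimate worse than large ones
  rec2 <- recovery_experiment(1.4, 10, c(5000, 100000), vocab_size = 2000,
                              replicates = 3, seed = 5)
  sm2 <- attr(rec2, "summary")
  expect_gt(abs(sm2$bias_alpha[sm2$n_tokens == 5000]),
            abs(sm2$bias_alpha[sm2$n_tokens == 100000]))
})
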