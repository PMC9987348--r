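# Shared fixtures, all built in code.

# A small CHAT transcript exercising headers, main tiers, %mor, continuation
# lines and annotation codes.
chat_fixture_lines <- function() {
  c("@UTF8",
    "@Begin",
    "@Languages:\teng",
    "@Participants:\tCHI Jane Target_Child, MOT Mary Mother, INV Pat Investigator",
    "@ID:\teng|demo|CHI|1;0.|female|||Target_Child|||",
    "@ID:\teng|demo|MOT|||||Mother|||",
    "@ID:\teng|demo|INV|||||Investigator|||",
    "*MOT:\tthe doggy .",
    "%mor:\tdet|the n|doggy .",
    "*CHI:\tdoggy .",
    "*INV:\twhere is the bunny ?",
    "%mor:\tadv|where v|is det|the n|bunny ?",
    "*MOT:\t&=laughs xxx doggy",
    "\t[= comment] again .",
    "@End")
}

# A ZM fit on a freshly generated stream, via the standard pipeline path.
fit_synthetic <- function(alpha, beta, vocab, n, seed, tie_seed = seed) {
  spec <- synthetic_spec(alpha, beta, vocab, n, seed = seed)
  fit_zm(assign_ranks(build_table(sample_zm(spec)), tie_seed = tie_seed))
}

# Exhaustive grid-search oracle for the ZM MLE (independent of fit_zm's
# optimizer): evaluates the log-likelihood on a full (alpha, beta) grid.
grid_oracle <- function(freqs, alphas = seq(0.5, 3, by = 0.01),
                        betas = seq(0, 5, by = 0.05)) {
  best <- c(alpha = NA_real_, beta = NA_real_)
  best_ll <- -Inf
  r <- seq_along(freqs)
  total <- sum(freqs)
  for (b in betas) {
    lr <- log(r + b)
    for (a in alphas) {
      lw <- -a * lr
      m <- max(lw)
      ll <- sum(freqs * lw) - total * (m + log(sum(exp(lw - m))))
      if (ll > best_ll) {
        best_ll <- ll
        best <- c(alpha = a, beta = b)
      }
    }
  }
  best
}

# Draw n values from a discrete power law p(x) ~ x^(-a), x >= 1, by inverse
# CDF on a truncated support (truncation mass is negligible for a > 1.5).
draw_discrete_powerlaw <- function(a, n, seed, max_x = 1e5) {
  w <- (1:max_x)^(-a)
  set.seed(seed)
  sample.int(max_x, n, replace = TRUE, prob = w / sum(w))
}
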