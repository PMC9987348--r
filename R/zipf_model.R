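# Core model: the Zipf-Mandelbrot law f(r) ~ 1 / (r + beta)^alpha over
# frequency ranks r = 1..N, fitted to observed rank-frequency distributions
# by maximum likelihood, with correlation-based goodness of fit.

zm_check_params <- function(alpha, beta) {
  if (!is.finite(alpha) || alpha <= 0) stop("alpha must be positive and finite")
  if (!is.finite(beta) || beta <= -1) {
    stop("beta must satisfy r + beta > 0 for all ranks (beta > -1)")
  }
  invisible(TRUE)
}

# log of the unnormalized weights, and the log normalizer
zm_logw <- function(alpha, beta, n_ranks) -alpha * log(seq_len(n_ranks) + beta)

#' Zipf-Mandelbrot probability mass function over ranks
#'
#' `p(r) = (r + beta)^(-alpha) / sum_{r'=1..N} (r' + beta)^(-alpha)` for ranks
#' `r = 1..N`. Computed in log space, so extreme parameter values (large
#' `alpha`, large `beta`) do not underflow.
#'
#' @param alpha Power-law exponent (> 0). Larger values give steeper
#'   distributions.
#' @param beta Mandelbrot shift (> -1; >= 0 in all fitted results), the
#'   low-rank correction to the classic Zipf law.
#' @param n_ranks Number of ranks N (>= 1).
#' @return Numeric probability vector of length `n_ranks`; sums to 1 and is
#'   strictly decreasing.
#' @examples
#' zm_pmf(2, 0, 3)  # 0.7347 0.1837 0.0816
#' @export
zm_pmf <- function(alpha, beta, n_ranks) {
  zm_check_params(alpha, beta)
  stopifnot(n_ranks >= 1)
  lw <- zm_logw(alpha, beta, n_ranks)
  exp(lw - logsumexp(lw))
}

#' Multinomial log-likelihood of a ranked distribution under the ZM law
#'
#' `sum_r f(r) log p(r)` with `p` the [zm_pmf()] over the observed number of
#' types. Frequencies may be fractional (relative-frequency inputs).
#'
#' @param x A `ranked_dist`, or a numeric vector of rank-ordered frequencies.
#' @param alpha,beta ZM parameters.
#' @return The log-likelihood (finite for valid parameters).
#' @export
zm_loglik <- function(x, alpha, beta) {
  f <- if (inherits(x, "ranked_dist")) x$frequencies else as.numeric(x)
  stopifnot(length(f) >= 1)
  zm_check_params(alpha, beta)
  lw <- zm_logw(alpha, beta, length(f))
  sum(f * lw) - sum(f) * logsumexp(lw)
}

#' Expected rank frequencies under fitted ZM parameters
#'
#' The model's predicted frequency at each rank: [zm_pmf()] multiplied by the
#' total token count.
#'
#' @param alpha,beta ZM parameters.
#' @param n_ranks Number of ranks.
#' @param total_tokens Total token count (> 0).
#' @return Numeric vector summing to `total_tokens` (within float tolerance).
#' @export
expected_frequencies <- function(alpha, beta, n_ranks, total_tokens) {
  stopifnot(total_tokens > 0)
  zm_pmf(alpha, beta, n_ranks) * total_tokens
}

#' Is a fitted expected distribution degenerate?
#'
#' A fit is flagged degenerate when its expected distribution cannot support a
#' correlation-based evaluation: either essentially all probability mass sits
#' on rank 1 (`p(1) > 1 - 1e-9`), or the unnormalized weight
#' `(1 + beta)^(-alpha)` underflows below the smallest normal double, so the
#' expected vector is not representable in ordinary double-precision
#' arithmetic. The second condition is what extreme preposition-style fits
#' (alpha of order 100) trigger: direct evaluation of the weights collapses
#' the expected distribution onto rank 1.
#'
#' @param alpha,beta ZM parameters.
#' @param n_ranks Number of ranks.
#' @return Logical flag.
#' @export
zm_degenerate <- function(alpha, beta, n_ranks) {
  zm_check_params(alpha, beta)
  if (-alpha * log1p(beta) < log(.Machine$double.xmin)) return(TRUE)
  p1 <- zm_pmf(alpha, beta, n_ranks)[1]
  p1 > 1 - 1e-9
}

# correlations of observed vs expected frequencies, no input checks
zm_correlations <- function(f, alpha, beta) {
  n <- length(f)
  total <- sum(f)
  if (zm_degenerate(alpha, beta, n)) {
    return(list(pearson_linear = NA_real_, pearson_loglog = NA_real_,
                degenerate = TRUE))
  }
  e <- zm_pmf(alpha, beta, n) * total
  if (stats::sd(e) == 0 || stats::sd(f) == 0) {
    return(list(pearson_linear = NA_real_, pearson_loglog = NA_real_,
                degenerate = TRUE))
  }
  keep <- f > 0 & e > 0
  ll <- if (sum(keep) >= 3 && stats::sd(log(f[keep])) > 0) {
    stats::cor(log(f[keep]), log(e[keep]))
  } else NA_real_
  list(pearson_linear = stats::cor(f, e), pearson_loglog = ll,
       degenerate = FALSE)
}

#' Goodness of fit of ZM parameters to a ranked distribution
#'
#' Pearson correlation between the observed and the expected frequency
#' vectors (observed vs expected frequency, not frequency vs rank), plus the
#' same correlation on a log-log scale (restricted to ranks where both are
#' positive). When the expected distribution is degenerate (see
#' [zm_degenerate()]) correlations are reported absent (`NA`), which is a
#' reported state rather than an error.
#'
#' @param ranked A `ranked_dist` (frequencies must be non-increasing), or a
#'   non-increasing numeric frequency vector.
#' @param alpha,beta ZM parameters.
#' @return List with `pearson_linear`, `pearson_loglog`, `degenerate`.
#' @export
evaluate_fit <- function(ranked, alpha, beta) {
  f <- if (inherits(ranked, "ranked_dist")) ranked$frequencies
       else as.numeric(ranked)
  stopifnot(length(f) >= 1)
  if (is.unsorted(-f)) {
    stop("frequencies must be non-increasing in rank; rank the table first")
  }
  zm_correlations(f, alpha, beta)
}

# default multi-start schedule
zm_default_starts <- function() {
  expand.grid(alpha = c(0.8, 1.2, 1.6, 3, 10, 50),
              beta = c(0.1, 1, 10, 100))
}

#' Fit the Zipf-Mandelbrot law by maximum likelihood
#'
#' Maximizes the multinomial log-likelihood of the observed rank-frequency
#' distribution over (alpha, beta), using bounded quasi-Newton (L-BFGS-B)
#' restarted from a fixed grid of starting values, so the result is
#' deterministic. The number of ranks is the observed number of types; no
#' unseen-type correction is applied.
#'
#' @param x A `ranked_dist` (see [assign_ranks()]) or a numeric vector of
#'   frequencies in rank order; at least 2 ranks.
#' @param alpha_bounds,beta_bounds Box constraints; the defaults
#'   `(0.05, 200]` and `[0, 1000]` are wide enough for the extreme fits seen
#'   in closed-class words.
#' @param starts Data frame of starting values (columns `alpha`, `beta`);
#'   `NULL` for the default 6 x 4 grid.
#' @param check_monotone Require the frequency vector to be non-increasing
#'   (the rank-ordered case). Disabled for split-half fits, where frequencies
#'   taken from the other half need not be monotone.
#' @return An object of class `zm_fit`: `alpha`, `beta`, `log_likelihood`,
#'   `pearson_linear`, `pearson_loglog`, `degenerate`, `n_types`, `n_tokens`,
#'   `method`, and `convergence` diagnostics (objective value per start).
#' @examples
#' ft <- build_table(sample(c("a", "b", "c"), 500, TRUE, prob = c(.6, .3, .1)))
#' fit_zm(assign_ranks(ft))
#' @export
fit_zm <- function(x, alpha_bounds = c(0.051, 200), beta_bounds = c(0, 1000),
                   starts = NULL, check_monotone = TRUE) {
  f <- if (inherits(x, "ranked_dist")) x$frequencies else as.numeric(x)
  if (length(f) < 2) stop("need at least 2 ranks to fit")
  if (any(f < 0) || sum(f) <= 0) stop("frequencies must be non-negative")
  if (check_monotone && is.unsorted(-f)) {
    stop("frequencies must be non-increasing in rank; rank the table first")
  }
  n <- length(f); r <- seq_len(n); total <- sum(f)
  nll <- function(par) {
    lw <- -par[1] * log(r + par[2])
    -(sum(f * lw) / total - logsumexp(lw))
  }
  if (is.null(starts)) starts <- zm_default_starts()
  starts$alpha <- pmin(pmax(starts$alpha, alpha_bounds[1]), alpha_bounds[2])
  starts$beta <- pmin(pmax(starts$beta, beta_bounds[1]), beta_bounds[2])

  best <- NULL
  diag <- data.frame(start_alpha = starts$alpha, start_beta = starts$beta,
                     value = NA_real_, convergence = NA_integer_)
  for (i in seq_len(nrow(starts))) {
    o <- tryCatch(
      stats::optim(c(starts$alpha[i], starts$beta[i]), nll,
                   method = "L-BFGS-B",
                   lower = c(alpha_bounds[1], beta_bounds[1]),
                   upper = c(alpha_bounds[2], beta_bounds[2]),
                   control = list(factr = 1e6, maxit = 500)),
      error = function(e) NULL)
    if (is.null(o)) next
    diag$value[i] <- o$value
    diag$convergence[i] <- o$convergence
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best)) stop("ZM fit failed from every starting value")
  if (best$convergence != 0 && all(diag$convergence != 0, na.rm = TRUE)) {
    stop("ZM fit did not converge from any start; best objective ",
         format(best$value), " at alpha=", format(best$par[1]),
         ", beta=", format(best$par[2]))
  }
  alpha <- best$par[1]; beta <- best$par[2]
  corr <- zm_correlations(f, alpha, beta)
  structure(list(alpha = alpha, beta = beta,
                 log_likelihood = zm_loglik(f, alpha, beta),
                 pearson_linear = corr$pearson_linear,
                 pearson_loglog = corr$pearson_loglog,
                 degenerate = corr$degenerate,
                 n_types = n, n_tokens = total,
                 method = "full",
                 convergence = diag),
            class = "zm_fit")
}

#' @export
print.zm_fit <- function(x, digits = 4, ...) {
  cat("Zipf-Mandelbrot fit (", x$method, "): ",
      x$n_types, " types, ", format(x$n_tokens, big.mark = ","),
      " tokens\n", sep = "")
  cat("  alpha = ", format(x$alpha, digits = digits),
      ", beta = ", format(x$beta, digits = digits),
      ", logLik = ", format(x$log_likelihood, digits = digits), "\n", sep = "")
  if (isTRUE(x$degenerate)) {
    cat("  degenerate expected distribution: correlations not defined\n")
  } else {
    cat("  Pearson r (obs vs expected) = ",
        format(x$pearson_linear, digits = digits),
        ", log-log r = ", format(x$pearson_loglog, digits = digits),
        "\n", sep = "")
  }
  invisible(x)
}

#' Split-half estimation of ZM parameters
#'
#' Decouples the rank and frequency measurements: each token is assigned
#' independently to half A or half B with probability 1/2; word ranks are
#' computed from half A, the frequency at each rank is read from half B, and
#' the ZM law is fitted to the resulting rank-frequency pairs. By default only
#' words observed in both halves are used (`missing = "drop"`); with
#' `missing = "zero"` words absent from half B keep their A-rank with
#' frequency zero.
#'
#' @param tokens Character token stream, large enough that both halves are
#'   non-empty.
#' @param seed RNG seed driving the binomial split and rank tie-breaking.
#' @param missing Treatment of words seen in only one half.
#' @return A `zm_fit` with `method = "split_half"`.
#' @export
split_half_fit <- function(tokens, seed = 0L, missing = c("drop", "zero")) {
  missing <- match.arg(missing)
  stopifnot(length(tokens) >= 2)
  g <- with_seed(seed, stats::rbinom(length(tokens), 1L, 0.5))
  a <- tokens[g == 1L]; b <- tokens[g == 0L]
  if (!length(a) || !length(b)) stop("one split half is empty; stream too small")
  ranked_a <- assign_ranks(build_table(a), tie_seed = seed)
  cnt_b <- build_table(b)$counts
  f <- unname(cnt_b[ranked_a$words])
  f[is.na(f)] <- 0
  if (missing == "drop") f <- f[f > 0]
  if (length(f) < 2) stop("no overlap between split halves")
  fit <- fit_zm(f, check_monotone = FALSE)
  fit$method <- "split_half"
  fit
}

# Hurwitz zeta sum_{k>=0} (q + k)^(-a): truncated sum + Euler-Maclaurin tail.
hurwitz_zeta <- function(a, q, terms = 1000L) {
  k <- 0:(terms - 1L)
  s <- sum((q + k)^(-a))
  m <- q + terms
  s + m^(1 - a) / (a - 1) + 0.5 * m^(-a) + a * m^(-a - 1) / 12
}

#' Discrete power-law fit with KS-optimal threshold
#'
#' The threshold-based alternative to whole-distribution ZM fitting: for each
#' candidate threshold `x_min` among the observed values, the exponent of a
#' discrete power law `p(x) ~ x^(-a)`, `x >= x_min`, is estimated by maximum
#' likelihood (Hurwitz-zeta normalizer), and the `x_min` minimizing the
#' Kolmogorov-Smirnov distance between the empirical and model CDFs of the
#' tail is selected.
#'
#' @param values Numeric vector of at least 10 positive values (typically the
#'   frequency counts of all word types). Must not be all equal.
#' @param exponent_bounds Search interval for the exponent.
#' @param max_candidates Cap on the number of `x_min` candidates; when the
#'   number of unique values exceeds it, quantile-spaced candidates are used.
#' @return An object of class `clauset_fit`: `exponent`, `x_min`,
#'   `ks_distance`, and `n_tail` (values at or above `x_min`).
#' @export
fit_clauset <- function(values, exponent_bounds = c(1.01, 20),
                        max_candidates = 60L) {
  values <- as.numeric(values)
  stopifnot(all(values > 0))
  if (length(values) < 10) stop("need at least 10 values")
  ux <- sort(unique(values))
  if (length(ux) < 2) stop("degenerate input: all values equal")
  # candidates must leave a tail of at least 10 values
  cand <- ux[vapply(ux, function(x) sum(values >= x) >= 10, logical(1))]
  if (!length(cand)) cand <- ux[1]
  if (length(cand) > max_candidates) {
    cand <- unique(stats::quantile(cand, probs = seq(0, 1,
                                                     length.out = max_candidates),
                                   type = 1, names = FALSE))
  }
  best <- NULL
  for (xm in cand) {
    tail_v <- values[values >= xm]
    slog <- sum(log(tail_v)); n <- length(tail_v)
    opt <- stats::optimize(function(a) n * log(hurwitz_zeta(a, xm)) + a * slog,
                           interval = exponent_bounds)
    a <- opt$minimum
    z <- hurwitz_zeta(a, xm)
    uxt <- sort(unique(tail_v))
    emp <- cumsum(tabulate(match(sort(tail_v), uxt))) / n
    mod <- 1 - vapply(uxt, function(x) hurwitz_zeta(a, x + 1), numeric(1)) / z
    d <- max(abs(emp - mod))
    if (is.null(best) || d < best$ks_distance) {
      best <- list(exponent = a, x_min = xm, ks_distance = d, n_tail = n)
    }
  }
  structure(best, class = "clauset_fit")
}

#' @export
print.clauset_fit <- function(x, digits = 4, ...) {
  cat("Discrete power-law fit: exponent = ", format(x$exponent, digits = digits),
      ", x_min = ", format(x$x_min),
      ", KS distance = ", format(x$ks_distance, digits = digits),
      " (", x$n_tail, " tail values)\n", sep = "")
  invisible(x)
}
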