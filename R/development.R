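# Developmental analyses: six-month age bins and mixed-effect age trends.

age_bin_label <- function(start, end) {
  sprintf("%d;%d–%d;%d", start %/% 12L, start %% 12L,
          end %/% 12L, end %% 12L)
}

#' Pool adult tokens into six-month age bins
#'
#' Bins tile the age axis in six-month steps (`0;0-0;5`, `0;6-0;11`, ...);
#' each transcript's tokens land in exactly one bin according to the target
#' child's age at recording. Transcripts without a parseable age are excluded
#' from the bins and counted.
#'
#' @param corpus A [token_corpus()] whose metadata carries
#'   `child_age_months`.
#' @param bin_months Bin width in months (default 6).
#' @return List of bins ordered by age, each `list(start_months, end_months,
#'   label, tokens, n_tokens, n_types)`; the token count of unaged transcripts
#'   is attached as `attr(, "unaged_tokens")`.
#' @export
bin_by_age <- function(corpus, bin_months = 6L) {
  ages <- vapply(corpus, function(x) {
    a <- x$meta$child_age_months
    if (is.null(a) || is.na(a)) NA_integer_ else as.integer(a)
  }, integer(1))
  unaged <- sum(vapply(corpus[is.na(ages)], function(x) length(x$tokens),
                       integer(1)))
  keep <- which(!is.na(ages))
  starts <- bin_months * (ages[keep] %/% bin_months)
  bins <- lapply(sort(unique(starts)), function(s) {
    toks <- unlist(lapply(corpus[keep[starts == s]], `[[`, "tokens"),
                   use.names = FALSE)
    list(start_months = s, end_months = s + bin_months - 1L,
         label = age_bin_label(s, s + bin_months - 1L),
         tokens = toks, n_tokens = length(toks),
         n_types = length(unique(toks)))
  })
  attr(bins, "unaged_tokens") <- unaged
  bins
}

#' Fit the ZM law per age bin, subject to a minimal corpus size
#'
#' Bins at or above `min_tokens` are fitted (MLE plus correlation-based
#' evaluation); smaller bins are summarized only — their token and type counts
#' are reported with absent parameters, since estimates below the bound are
#' unstable.
#'
#' @param bins Output of [bin_by_age()].
#' @param min_tokens Minimal bin size in tokens for fitting (default 50,000).
#' @param tie_seed Tie-breaking seed for ranking.
#' @return Data frame with one row per bin: `age_range`, `start_months`,
#'   `n_tokens`, `n_types`, `min_count`, `max_count`, `min_per_million`,
#'   `max_per_million`, `alpha`, `beta`, `pearson_r`, `fitted`.
#' @export
fit_bins <- function(bins, min_tokens = 50000L, tie_seed = 0L) {
  rows <- lapply(bins, function(b) {
    tab <- build_table(b$tokens)
    sm <- summarize_table(tab)
    row <- data.frame(age_range = b$label, start_months = b$start_months,
                      n_tokens = sm$n_tokens, n_types = sm$n_types,
                      min_count = sm$min_count, max_count = sm$max_count,
                      min_per_million = sm$min_per_million,
                      max_per_million = sm$max_per_million,
                      alpha = NA_real_, beta = NA_real_,
                      pearson_r = NA_real_, fitted = FALSE,
                      stringsAsFactors = FALSE)
    if (b$n_tokens >= min_tokens && sm$n_types >= 2) {
      fit <- fit_zm(assign_ranks(tab, tie_seed = tie_seed))
      row$alpha <- fit$alpha; row$beta <- fit$beta
      row$pearson_r <- fit$pearson_linear
      row$fitted <- TRUE
    }
    row
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) {
    df <- data.frame(age_range = character(0), start_months = integer(0),
                     n_tokens = integer(0), n_types = integer(0),
                     min_count = numeric(0), max_count = numeric(0),
                     min_per_million = numeric(0), max_per_million = numeric(0),
                     alpha = numeric(0), beta = numeric(0),
                     pearson_r = numeric(0), fitted = logical(0))
  }
  rownames(df) <- NULL
  df
}

#' Age trend of a fitted quantity across languages
#'
#' Mixed-effect regression of a per-bin quantity (alpha or Pearson's r) on the
#' bin's start age in months (centred), with the maximal random-effect
#' structure for language that converges: random intercept and age slope by
#' language, simplified to a random intercept, then to a fixed-effects
#' regression when fitting fails or is singular.
#'
#' @param per_bin_fits Data frame with one row per fitted bin and columns for
#'   the response, `start_months`, and a language identifier.
#' @param response Which column to model: `"alpha"` or `"pearson_r"` (or any
#'   column name present in the data).
#' @param language_col,age_col Column names for the grouping and age
#'   variables.
#' @return List with `slope` (change per month), `std_error`, `p_value`,
#'   `response`, and `model` (the random-effect structure actually used).
#'   P-values for mixed models use the Satterthwaite approximation
#'   (lmerTest); the fixed-effects fallback uses the t-test from `lm`.
#' @export
age_trend <- function(per_bin_fits, response = c("alpha", "pearson_r"),
                      language_col = "language", age_col = "start_months") {
  response <- match.arg(response, choices = unique(c(response,
                                                     names(per_bin_fits))))
  d <- per_bin_fits[!is.na(per_bin_fits[[response]]), , drop = FALSE]
  d$.y <- d[[response]]
  d$.lang <- factor(d[[language_col]])
  d$.age <- d[[age_col]] - mean(d[[age_col]])
  per_lang <- table(d$.lang)
  if (sum(per_lang >= 2) < 2) {
    stop("need at least 2 bins per language for at least 2 languages")
  }

  fit_quiet <- function(formula) {
    tryCatch({
      m <- suppressMessages(suppressWarnings(
        lmerTest::lmer(formula, data = d, REML = TRUE)))
      if (lme4::isSingular(m, tol = 1e-4)) NULL else m
    }, error = function(e) NULL)
  }
  m <- fit_quiet(.y ~ .age + (1 + .age | .lang))
  model_lab <- "random intercept and age slope by language"
  if (is.null(m)) {
    m <- fit_quiet(.y ~ .age + (1 | .lang))
    model_lab <- "random intercept by language"
  }
  if (is.null(m)) {
    lm_fit <- stats::lm(.y ~ .age, data = d)
    cf <- summary(lm_fit)$coefficients
    return(list(slope = cf[".age", "Estimate"],
                std_error = cf[".age", "Std. Error"],
                p_value = cf[".age", "Pr(>|t|)"],
                response = response, model = "fixed effects only"))
  }
  cf <- stats::coef(summary(m))
  list(slope = cf[".age", "Estimate"],
       std_error = cf[".age", "Std. Error"],
       p_value = cf[".age", "Pr(>|t|)"],
       response = response, model = model_lab)
}
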