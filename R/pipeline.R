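# End-to-end orchestration of the three analyses over one or more corpora.

# Normalize a corpus argument (directory, file paths, or parsed transcripts)
# to a list of chat_transcript objects.
load_transcripts <- function(x, lowercase = TRUE) {
  if (is.character(x)) return(read_chat_corpus(x, lowercase = lowercase))
  if (is.list(x) && all(vapply(x, inherits, logical(1), "chat_transcript"))) {
    return(x)
  }
  stop("corpus must be a directory, CHAT file paths, or parsed transcripts")
}

#' Whole-corpus analysis across languages
#'
#' For each language: pools all adult tokens, summarizes the corpus, fits the
#' ZM law (optionally also by split-half), cuts conversationally continuous
#' samples of a fixed size and fits each, and compares the per-sample alpha
#' estimates across languages by one-way ANOVA. Languages below the
#' minimum-token threshold are excluded and listed.
#'
#' @param corpora Named list (language -> directory, CHAT file paths, or
#'   parsed transcripts).
#' @param selection A [corpus_selection()].
#' @param sample_target Size of continuous subsamples in tokens
#'   (default 100,000).
#' @param min_samples Minimum number of subsamples for a language to enter
#'   the cross-language comparison (default 3).
#' @param split_half Also compute a split-half fit per language.
#' @param tie_seed,seed Seeds for tie-breaking and the split-half split.
#' @return List of class `study1_result`: `table` (one row per language with
#'   the summary columns, alpha, beta, Pearson's r), `sample_fits`,
#'   `anova` (or `NULL` when fewer than two languages qualify), `excluded`.
#' @export
run_study1 <- function(corpora, selection = corpus_selection(),
                       sample_target = 100000L, min_samples = 3L,
                       split_half = FALSE, tie_seed = 0L, seed = 0L) {
  stopifnot(length(corpora) >= 1, !is.null(names(corpora)))
  rows <- list(); sample_rows <- list(); excluded <- character(0)
  for (lang in names(corpora)) {
    tc <- token_corpus(load_transcripts(corpora[[lang]]), selection)
    tokens <- unlist(lapply(tc, `[[`, "tokens"), use.names = FALSE)
    if (length(tokens) < selection$min_corpus_tokens) {
      message("excluding ", lang, ": ", length(tokens),
              " adult tokens < threshold ", selection$min_corpus_tokens)
      excluded <- c(excluded, lang)
      next
    }
    tab <- build_table(tokens)
    sm <- summarize_table(tab)
    fit <- fit_zm(assign_ranks(tab, tie_seed = tie_seed))
    row <- data.frame(language = lang, n_tokens = sm$n_tokens,
                      n_types = sm$n_types,
                      min_count = sm$min_count, max_count = sm$max_count,
                      min_per_million = sm$min_per_million,
                      max_per_million = sm$max_per_million,
                      alpha = fit$alpha, beta = fit$beta,
                      pearson_r = fit$pearson_linear,
                      stringsAsFactors = FALSE)
    if (split_half) {
      sh <- split_half_fit(tokens, seed = seed)
      row$alpha_split <- sh$alpha
      row$beta_split <- sh$beta
    }
    rows[[lang]] <- row
    slices <- suppressWarnings(continuous_samples(tc, sample_target))
    if (length(slices)) {
      fits <- lapply(slices, function(s)
        fit_zm(assign_ranks(build_table(s$tokens), tie_seed = tie_seed)))
      sample_rows[[lang]] <- data.frame(
        language = lang, sample = seq_along(slices),
        actual_size = vapply(slices, `[[`, numeric(1), "actual_size"),
        alpha_hat = vapply(fits, `[[`, numeric(1), "alpha"),
        beta_hat = vapply(fits, `[[`, numeric(1), "beta"),
        pearson_r = vapply(fits, `[[`, numeric(1), "pearson_linear"),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("no language passed the corpus-size threshold")
  table <- do.call(rbind, rows); rownames(table) <- NULL
  samples <- if (length(sample_rows)) {
    s <- do.call(rbind, sample_rows); rownames(s) <- NULL; s
  }
  aov_res <- NULL
  if (!is.null(samples)) {
    eligible <- names(which(table(samples$language) >= min_samples))
    s <- samples[samples$language %in% eligible, , drop = FALSE]
    if (length(unique(s$language)) >= 2) {
      aov_res <- compare_groups(s$alpha_hat, s$language)
    }
  }
  structure(list(table = table, sample_fits = samples, anova = aov_res,
                 excluded = excluded),
            class = "study1_result")
}

#' Developmental analysis: age bins and age trends
#'
#' Bins each language's adult tokens by child age in six-month bins, fits
#' every bin at or above the minimum size, and — when at least two languages
#' contribute at least two fitted bins each — estimates the age trend of
#' alpha and of Pearson's r with mixed-effect models.
#'
#' @param corpora Named list (language -> directory, files, or transcripts).
#' @param selection A [corpus_selection()].
#' @param min_bin_tokens Minimal bin size for fitting (default 50,000).
#' @param bin_months Bin width in months (default 6).
#' @param tie_seed Tie-breaking seed.
#' @return List of class `study2_result`: `bins` (per-language per-bin
#'   table), `trend_alpha`, `trend_pearson` (each `NULL` when too few usable
#'   bins).
#' @export
run_study2 <- function(corpora, selection = corpus_selection(),
                       min_bin_tokens = 50000L, bin_months = 6L,
                       tie_seed = 0L) {
  stopifnot(length(corpora) >= 1, !is.null(names(corpora)))
  per_lang <- lapply(names(corpora), function(lang) {
    tc <- token_corpus(load_transcripts(corpora[[lang]]), selection)
    bins <- bin_by_age(tc, bin_months = bin_months)
    if (!length(bins)) return(NULL)
    df <- fit_bins(bins, min_tokens = min_bin_tokens, tie_seed = tie_seed)
    df$language <- lang
    df
  })
  bins <- do.call(rbind, per_lang)
  if (is.null(bins) || !nrow(bins)) stop("no age-binnable data found")
  rownames(bins) <- NULL
  fitted <- bins[bins$fitted, , drop = FALSE]
  usable <- sum(table(fitted$language) >= 2) >= 2
  trend_a <- trend_r <- NULL
  if (usable) {
    trend_a <- age_trend(fitted, response = "alpha")
    trend_r <- age_trend(fitted, response = "pearson_r")
  } else {
    message("fewer than 2 languages with 2+ fitted bins: trend models skipped")
  }
  structure(list(bins = bins, trend_alpha = trend_a, trend_pearson = trend_r),
            class = "study2_result")
}

#' Part-of-speech analysis
#'
#' For each language and POS category: extracts the category's tokens via the
#' morphology tier, applies the exclusion list (the surrogate for manual
#' cleaning) and reports the tagging error rate, then fits the ZM law with
#' degeneracy handling. Categories with no tokens yield a zero row, flagged.
#'
#' @param corpora Named list (language -> directory, files, or transcripts);
#'   transcripts must carry `%mor` tiers.
#' @param profile Tag profile as in [default_pos_profile()], or a named list
#'   of per-language profiles keyed like `corpora`.
#' @param exclusions Optional named list: `exclusions[[language]][[category]]`
#'   is a character vector (or a file readable by [read_exclusion_list()]).
#' @param selection A [corpus_selection()].
#' @param tie_seed Tie-breaking seed.
#' @return Data frame of class `study3_result`: one row per language x
#'   category with tokens, types, frequency range, `error_rate`, `alpha`,
#'   `beta`, `pearson_r`, `degenerate`, `low_reliability`.
#' @export
run_study3 <- function(corpora, profile = default_pos_profile(),
                       exclusions = NULL, selection = corpus_selection(),
                       tie_seed = 0L) {
  stopifnot(length(corpora) >= 1, !is.null(names(corpora)))
  per_language_profiles <- !is.null(names(profile)) &&
    all(names(corpora) %in% names(profile)) &&
    all(vapply(profile, is.list, logical(1))) &&
    !any(c("noun", "verb", "adjective", "preposition") %in% names(profile))
  rows <- list()
  for (lang in names(corpora)) {
    prof <- if (per_language_profiles) profile[[lang]] else profile
    utts <- lapply(load_transcripts(corpora[[lang]]), filter_adult, selection)
    for (cat in names(prof)) {
      toks <- tryCatch(extract_pos_tokens(utts, prof[[cat]]),
                       error = function(e) character(0))
      if (!length(toks)) {
        rows[[paste(lang, cat)]] <- data.frame(
          language = lang, pos = cat, n_tokens = 0, n_types = 0,
          min_count = NA_real_, max_count = NA_real_,
          error_rate = NA_real_, alpha = NA_real_, beta = NA_real_,
          pearson_r = NA_real_, degenerate = NA, low_reliability = NA,
          empty = TRUE, stringsAsFactors = FALSE)
        next
      }
      tab <- build_table(toks)
      excl <- exclusions[[lang]][[cat]]
      if (is.character(excl) && length(excl) == 1L && file.exists(excl)) {
        excl <- read_exclusion_list(excl)
      }
      rate <- 0
      if (!is.null(excl) && length(excl)) {
        res <- apply_exclusions(tab, excl)
        tab <- res$table
        rate <- res$error_rate
      }
      pf <- fit_pos(rep(names(tab$counts), times = tab$counts),
                    tie_seed = tie_seed)
      rows[[paste(lang, cat)]] <- data.frame(
        language = lang, pos = cat, n_tokens = pf$n_tokens,
        n_types = pf$n_types, min_count = pf$min_count,
        max_count = pf$max_count, error_rate = rate,
        alpha = pf$alpha, beta = pf$beta,
        pearson_r = pf$pearson_r, degenerate = pf$degenerate,
        low_reliability = pf$low_reliability, empty = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  if (all(vapply(rows, function(r) r$empty, logical(1)))) {
    stop("no morphology tags found in any corpus")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("study3_result", class(out))
  out
}

#' @export
print.study1_result <- function(x, ...) {
  cat("Whole-corpus ZM fits (", nrow(x$table), " language(s))\n", sep = "")
  print(x$table, digits = 4)
  if (!is.null(x$anova)) {
    cat(sprintf("Effect of language on alpha: F(%d, %d) = %.2f, p = %.3g\n",
                x$anova$df[1], x$anova$df[2], x$anova$statistic,
                x$anova$p_value))
  }
  if (length(x$excluded)) {
    cat("Excluded (below token threshold):",
        paste(x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
print.study2_result <- function(x, ...) {
  cat("Age-binned ZM fits\n")
  print(x$bins, digits = 4)
  for (tr in list(x$trend_alpha, x$trend_pearson)) {
    if (!is.null(tr)) {
      cat(sprintf("%s ~ age: slope %.5f / month (SE %.5f, p = %.3g; %s)\n",
                  tr$response, tr$slope, tr$std_error, tr$p_value, tr$model))
    }
  }
  invisible(x)
}
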