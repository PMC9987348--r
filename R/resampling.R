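# Subsampling and cross-group comparison: conversationally continuous
# samples, sample-size stability curves, and one-way ANOVA across groups.

#' Extract the adult token stream of a transcript
#'
#' @param transcript A `chat_transcript`.
#' @param selection A [corpus_selection()].
#' @return Character vector of adult tokens in utterance order.
#' @export
adult_tokens <- function(transcript, selection = corpus_selection()) {
  utt <- suppressMessages(filter_adult(transcript, selection))$utterances
  unlist(utt$tokens, use.names = FALSE) %||% character(0)
}

#' Reduce parsed transcripts to an ordered token corpus
#'
#' The working representation for sampling and age binning: one element per
#' transcript, holding its metadata and its adult token stream, ordered by
#' (corpus name, path) — the transcript ordering used for conversationally
#' continuous sampling.
#'
#' @param transcripts List of `chat_transcript` objects.
#' @param selection A [corpus_selection()].
#' @return A list of `list(meta, tokens)` elements, ordered by ordering key;
#'   class `token_corpus`.
#' @export
token_corpus <- function(transcripts, selection = corpus_selection()) {
  out <- lapply(transcripts, function(t) {
    list(meta = t$meta, tokens = adult_tokens(t, selection))
  })
  ord <- order(vapply(out, function(x) x$meta$corpus_name %||% "", character(1)),
               vapply(out, function(x) as.character(x$meta$ordering_key),
                      character(1)))
  structure(out[ord], class = "token_corpus")
}

#' Conversationally continuous samples of a target size
#'
#' Accumulates whole transcripts in corpus order, emitting a sample as soon as
#' the cumulative token count reaches the target, then continuing from the
#' next transcript. Transcripts are never split mid-file, so every sample is
#' conversationally continuous and its actual size is at least the target. A
#' trailing remainder below the target is discarded.
#'
#' @param corpus A [token_corpus()] (or plain list of `list(meta, tokens)`).
#' @param target Target sample size in tokens.
#' @return List of samples, each `list(tokens, source, target_size,
#'   actual_size)` where `source` holds the contributing transcript paths.
#'   Empty (with a warning) when the corpus is smaller than the target.
#' @export
continuous_samples <- function(corpus, target) {
  stopifnot(target > 0)
  samples <- list()
  cur_tokens <- list(); cur_src <- character(0); cur_n <- 0L
  for (tr in corpus) {
    cur_tokens[[length(cur_tokens) + 1L]] <- tr$tokens
    cur_src <- c(cur_src, tr$meta$path)
    cur_n <- cur_n + length(tr$tokens)
    if (cur_n >= target) {
      samples[[length(samples) + 1L]] <-
        list(tokens = unlist(cur_tokens, use.names = FALSE),
             source = cur_src, target_size = target, actual_size = cur_n)
      cur_tokens <- list(); cur_src <- character(0); cur_n <- 0L
    }
  }
  if (!length(samples)) {
    warning("corpus smaller than the target sample size; no samples emitted")
  } else if (cur_n > 0) {
    message("discarding trailing remainder of ", cur_n, " tokens")
  }
  samples
}

#' Stability of fitted parameters as a function of sample size
#'
#' For each sample size, builds replicate samples by randomly ordering the
#' transcripts and reading whole transcripts from the beginning until the
#' required token count is reached, fits the ZM law to each sample, and
#' summarizes the estimates per size. Shrinking replicate SD with growing
#' size indicates the minimal corpus size for stable estimation.
#'
#' @param corpus A [token_corpus()].
#' @param sizes Sample sizes in tokens (default 5,000 to 100,000 by 5,000).
#' @param replicates Replicate samples per size (default 10).
#' @param seed RNG seed; identical seeds give bit-identical curves.
#' @param tie_seed Tie-breaking seed for ranking.
#' @return Data frame with columns `sample_size`, `replicate`, `actual_size`,
#'   `alpha_hat`, `beta_hat`, `pearson_r`; a per-size summary (mean and SD of
#'   `alpha_hat`) is attached as `attr(, "summary")`. Sizes exceeding the
#'   corpus are skipped with a warning.
#' @export
stability_curve <- function(corpus, sizes = seq(5000, 100000, by = 5000),
                            replicates = 10L, seed = 0L, tie_seed = 0L) {
  total <- sum(vapply(corpus, function(x) length(x$tokens), integer(1)))
  if (any(sizes > total)) {
    warning("skipping sample sizes exceeding the corpus (",
            total, " tokens)")
    sizes <- sizes[sizes <= total]
  }
  rows <- with_seed(seed, {
    out <- list()
    for (s in sizes) {
      for (r in seq_len(replicates)) {
        ord <- sample.int(length(corpus))
        acc <- list(); n <- 0
        for (i in ord) {
          acc[[length(acc) + 1L]] <- corpus[[i]]$tokens
          n <- n + length(corpus[[i]]$tokens)
          if (n >= s) break
        }
        fit <- fit_zm(assign_ranks(build_table(unlist(acc, use.names = FALSE)),
                                   tie_seed = tie_seed))
        out[[length(out) + 1L]] <-
          data.frame(sample_size = s, replicate = r, actual_size = n,
                     alpha_hat = fit$alpha, beta_hat = fit$beta,
                     pearson_r = fit$pearson_linear)
      }
    }
    out
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) df <- data.frame(sample_size = numeric(0),
                                    replicate = integer(0),
                                    actual_size = numeric(0),
                                    alpha_hat = numeric(0),
                                    beta_hat = numeric(0),
                                    pearson_r = numeric(0))
  if (nrow(df)) {
    sm <- do.call(rbind, lapply(split(df, df$sample_size), function(d) {
      data.frame(sample_size = d$sample_size[1],
                 mean_alpha = mean(d$alpha_hat),
                 sd_alpha = stats::sd(d$alpha_hat),
                 mean_beta = mean(d$beta_hat),
                 sd_beta = stats::sd(d$beta_hat))
    }))
    rownames(sm) <- NULL
    attr(df, "summary") <- sm
  }
  df
}

#' One-way ANOVA of fitted parameters across groups
#'
#' Standard one-way analysis of variance of per-sample estimates (typically
#' alpha) across groups such as languages or language families.
#'
#' @param values Numeric vector of estimates.
#' @param groups Group labels, same length.
#' @return List with `statistic` (F), `df` (numerator, denominator degrees of
#'   freedom `(k-1, n-k)`) and `p_value`.
#' @examples
#' compare_groups(c(1, 2, 3, 2, 3, 4), rep(c("a", "b"), each = 3))
#' @export
compare_groups <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  g <- factor(groups)
  if (nlevels(g) < 2) stop("need at least 2 groups")
  sizes <- table(g)
  if (max(sizes) < 2) stop("need at least one group with 2 or more values")
  within_var <- tapply(values, g, function(v) {
    if (length(v) > 1) stats::var(v) else NA_real_
  })
  if (all(within_var == 0 | is.na(within_var))) {
    stop("zero within-group variance everywhere: F is undefined")
  }
  a <- stats::anova(stats::lm(values ~ g))
  list(statistic = a$`F value`[1],
       df = c(a$Df[1], a$Df[2]),
       p_value = a$`Pr(>F)`[1])
}
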