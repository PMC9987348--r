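# Synthetic corpora with known generating parameters, so the whole pipeline
# (parsing, filtering, ranking, fitting, binning, POS extraction) can be
# validated without access to real child-directed-speech corpora.

#' Specification of a synthetic corpus
#'
#' Describes a corpus of i.i.d. Zipf-Mandelbrot draws packed into utterances
#' and transcripts with age metadata, an admixture of child utterances (to
#' exercise speaker filtering), and optionally per-category POS structure
#' with aligned morphology tags. All randomness flows from the single seed.
#'
#' @param alpha,beta Generating ZM parameters.
#' @param vocab_size Vocabulary size (number of ranks).
#' @param n_tokens Number of adult tokens to generate.
#' @param utterance_len_mean Mean utterance length in tokens (shifted
#'   geometric, minimum 1); plumbing only, nothing downstream depends on it.
#' @param transcript_tokens Adult tokens per transcript before a new
#'   transcript is started (default 2,000).
#' @param age_schedule Integer vector of child ages in months assigned to
#'   transcripts in order (recycled); default 24 for all.
#' @param pos_profile Optional named list (names = category labels) of
#'   `list(alpha, beta, vocab, share)` per category; when present, tokens are
#'   drawn category-wise with `%mor` tags emitted.
#' @param child_fraction Fraction of utterances emitted under the child role
#'   (default 0.1); child tokens are extra draws, not counted in `n_tokens`.
#' @param seed Integer RNG seed.
#' @param language,corpus_name Header metadata.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(alpha, beta, vocab_size, n_tokens,
                           utterance_len_mean = 6, transcript_tokens = 2000L,
                           age_schedule = NULL, pos_profile = NULL,
                           child_fraction = 0.1, seed = 0L,
                           language = "eng", corpus_name = "synthcorp") {
  zm_check_params(alpha, beta)
  stopifnot(vocab_size >= 1, n_tokens >= 1, utterance_len_mean >= 1,
            transcript_tokens >= 1, child_fraction >= 0, child_fraction < 1)
  if (!is.null(pos_profile)) {
    stopifnot(!is.null(names(pos_profile)),
              all(vapply(pos_profile, function(p)
                all(c("alpha", "beta", "vocab", "share") %in% names(p)),
                logical(1))))
  }
  structure(list(alpha = alpha, beta = beta,
                 vocab_size = as.integer(vocab_size),
                 n_tokens = as.integer(n_tokens),
                 utterance_len_mean = utterance_len_mean,
                 transcript_tokens = as.integer(transcript_tokens),
                 age_schedule = age_schedule %||% 24L,
                 pos_profile = pos_profile,
                 child_fraction = child_fraction,
                 seed = as.integer(seed),
                 language = language, corpus_name = corpus_name),
            class = "synthetic_spec")
}

# fixed injective rank -> word form mapping, so the generating rank is
# recoverable from the form for diagnostics
word_forms <- function(n, prefix = "w") {
  sprintf(paste0(prefix, "%0", nchar(as.character(n)), "d"), seq_len(n))
}

# draw n ranks from the ZM pmf (uses the caller's RNG state)
draw_zm_words <- function(alpha, beta, vocab, n, prefix = "w") {
  word_forms(vocab, prefix)[sample.int(vocab, n, replace = TRUE,
                                       prob = zm_pmf(alpha, beta, vocab))]
}

# draw n tokens (and tags) under a POS profile (uses caller's RNG state)
draw_pos_words <- function(profile, n) {
  labs <- names(profile)
  shares <- vapply(profile, `[[`, numeric(1), "share")
  cat_idx <- sample.int(length(labs), n, replace = TRUE,
                        prob = shares / sum(shares))
  toks <- character(n); tags <- character(n)
  for (j in seq_along(labs)) {
    sel <- cat_idx == j
    if (!any(sel)) next
    p <- profile[[j]]
    tag <- p$tag %||% labs[j]
    toks[sel] <- draw_zm_words(p$alpha, p$beta, p$vocab, sum(sel),
                               prefix = paste0(tag, "_"))
    tags[sel] <- tag
  }
  list(tokens = toks, tags = tags)
}

#' Sample a token stream from the ZM law
#'
#' `n_tokens` independent draws of ranks from the generating pmf, mapped to a
#' fixed injective set of word forms. Bit-identical for identical specs.
#'
#' @param spec A [synthetic_spec()].
#' @return Character token stream of length `spec$n_tokens`.
#' @export
sample_zm <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed,
            draw_zm_words(spec$alpha, spec$beta, spec$vocab_size,
                          spec$n_tokens))
}

#' A uniform-distribution baseline stream
#'
#' Each type appears `floor(n_tokens / vocab_size)` or
#' `ceiling(n_tokens / vocab_size)` times, in shuffled order — the uniform
#' exposure regime used by most lab studies, against which the skewed
#' natural-language regime is contrasted.
#'
#' @param vocab_size Number of types (must not exceed `n_tokens`).
#' @param n_tokens Stream length.
#' @param seed RNG seed for the shuffle.
#' @return Character token stream of length `n_tokens`.
#' @export
uniform_corpus <- function(vocab_size, n_tokens, seed = 0L) {
  if (vocab_size > n_tokens) stop("vocab_size must not exceed n_tokens")
  base <- n_tokens %/% vocab_size
  extra <- n_tokens %% vocab_size
  counts <- rep(base, vocab_size) + c(rep(1L, extra),
                                      rep(0L, vocab_size - extra))
  stream <- rep(word_forms(vocab_size), times = counts)
  with_seed(seed, sample(stream))
}

#' Write a synthetic corpus as CHAT transcripts
#'
#' Packs the generated adult token stream into utterances (shifted-geometric
#' lengths) and transcripts (closing a transcript once it holds
#' `transcript_tokens` adult tokens), writes CHAT files with `@ID` headers
#' carrying the age schedule, interleaves child-role utterances at the
#' configured fraction, and emits aligned `%mor` tiers when a POS profile is
#' present. Re-reading the files with [parse_chat()] and [filter_adult()]
#' reproduces the adult token multiset exactly.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Output directory (created if needed).
#' @return Character vector of the written file paths, invisibly.
#' @export
make_corpus <- function(spec, dir) {
  stopifnot(inherits(spec, "synthetic_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(spec$seed, {
    if (is.null(spec$pos_profile)) {
      adult <- list(tokens = draw_zm_words(spec$alpha, spec$beta,
                                           spec$vocab_size, spec$n_tokens),
                    tags = NULL)
    } else {
      adult <- draw_pos_words(spec$pos_profile, spec$n_tokens)
    }
    p_geom <- 1 / spec$utterance_len_mean
    utt_len <- function() 1L + stats::rgeom(1L, p_geom)

    files <- character(0)
    tr_idx <- 0L
    pos <- 1L
    ages <- rep_len(spec$age_schedule, ceiling(spec$n_tokens /
                                                 spec$transcript_tokens) + 1L)
    while (pos <= spec$n_tokens) {
      tr_idx <- tr_idx + 1L
      age <- ages[tr_idx]
      age_str <- sprintf("%d;%02d.", age %/% 12L, age %% 12L)
      lines <- c("@UTF8", "@Begin",
                 paste0("@Languages:\t", spec$language),
                 paste0("@Participants:\tCHI Target Target_Child, ",
                        "MOT Mother Mother"),
                 sprintf("@ID:\t%s|%s|CHI|%s|female|||Target_Child|||",
                         spec$language, spec$corpus_name, age_str),
                 sprintf("@ID:\t%s|%s|MOT|||||Mother|||",
                         spec$language, spec$corpus_name))
      tr_tokens <- 0L
      while (tr_tokens < spec$transcript_tokens && pos <= spec$n_tokens) {
        if (spec$child_fraction > 0 &&
            stats::runif(1L) < spec$child_fraction) {
          k <- utt_len()
          ch <- draw_zm_words(spec$alpha, spec$beta, spec$vocab_size, k)
          lines <- c(lines, paste0("*CHI:\t", paste(ch, collapse = " "), " ."))
        }
        k <- min(utt_len(), spec$n_tokens - pos + 1L)
        sel <- pos:(pos + k - 1L)
        lines <- c(lines, paste0("*MOT:\t",
                                 paste(adult$tokens[sel], collapse = " "),
                                 " ."))
        if (!is.null(adult$tags)) {
          lines <- c(lines, paste0("%mor:\t",
                                   paste(adult$tags[sel], adult$tokens[sel],
                                         sep = "|", collapse = " ")))
        }
        pos <- pos + k
        tr_tokens <- tr_tokens + k
      }
      lines <- c(lines, "@End")
      f <- file.path(dir, sprintf("%s_%03d.cha", spec$corpus_name, tr_idx))
      writeLines(lines, f, useBytes = TRUE)
      files <- c(files, f)
    }
    invisible(files)
  })
}

#' Parameter-recovery experiment
#'
#' For every cell of a (alpha, beta, size) grid and every replicate:
#' generate a stream with [sample_zm()], rank it with random tie-breaking,
#' fit with [fit_zm()], and record the estimates. Fit failures are recorded
#' per row, not fatal.
#'
#' @param alphas,betas Generating parameter values (crossed).
#' @param sizes Token counts (crossed).
#' @param vocab_size Vocabulary size used throughout.
#' @param replicates Independent replicates per cell; 0 gives an empty
#'   report.
#' @param seed Master seed; per-replicate seeds are derived from it.
#' @return Data frame with columns `true_alpha`, `true_beta`, `n_tokens`,
#'   `replicate`, `alpha_hat`, `beta_hat`, `error`; per-cell bias and RMSE of
#'   the alpha estimate are attached as `attr(, "summary")`.
#' @export
recovery_experiment <- function(alphas, betas, sizes, vocab_size = 10000L,
                                replicates = 5L, seed = 0L) {
  grid <- expand.grid(true_alpha = alphas, true_beta = betas,
                      n_tokens = sizes, replicate = seq_len(replicates))
  if (!nrow(grid)) {
    return(data.frame(true_alpha = numeric(0), true_beta = numeric(0),
                      n_tokens = numeric(0), replicate = integer(0),
                      alpha_hat = numeric(0), beta_hat = numeric(0),
                      error = character(0)))
  }
  sub_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L,
                                          nrow(grid)))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    row <- data.frame(g, alpha_hat = NA_real_, beta_hat = NA_real_,
                      error = NA_character_, stringsAsFactors = FALSE)
    tryCatch({
      spec <- synthetic_spec(g$true_alpha, g$true_beta, vocab_size,
                             g$n_tokens, seed = sub_seeds[i])
      fit <- fit_zm(assign_ranks(build_table(sample_zm(spec)),
                                 tie_seed = sub_seeds[i]))
      row$alpha_hat <- fit$alpha
      row$beta_hat <- fit$beta
    }, error = function(e) row$error <<- conditionMessage(e))
    row
  })
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  ok <- df[is.na(df$error), , drop = FALSE]
  if (nrow(ok)) {
    key <- interaction(ok$true_alpha, ok$true_beta, ok$n_tokens, drop = TRUE)
    sm <- do.call(rbind, lapply(split(ok, key), function(d) {
      data.frame(true_alpha = d$true_alpha[1], true_beta = d$true_beta[1],
                 n_tokens = d$n_tokens[1],
                 bias_alpha = mean(d$alpha_hat - d$true_alpha),
                 rmse_alpha = sqrt(mean((d$alpha_hat - d$true_alpha)^2)),
                 bias_beta = mean(d$beta_hat - d$true_beta),
                 rmse_beta = sqrt(mean((d$beta_hat - d$true_beta)^2)))
    }))
    rownames(sm) <- NULL
    attr(df, "summary") <- sm
  }
  df
}
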