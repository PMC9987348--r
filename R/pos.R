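# Part-of-speech analyses: extraction by morphology-tier tags, manual
# exclusion lists as a surrogate for human cleaning, and per-category fits.

#' Default mapping from morphology-tier codes to POS categories
#'
#' Maps exact category codes on the `%mor` tier to the four analysed
#' categories. Codes are matched exactly (no subcategory absorption); edit
#' the returned list to build a per-language profile.
#'
#' @return Named list of character vectors of tag codes, one entry per
#'   category: `noun`, `verb`, `adjective`, `preposition`.
#' @export
default_pos_profile <- function() {
  list(noun = "n", verb = "v", adjective = "adj", preposition = "prep")
}

#' Extract the tokens of one POS category
#'
#' Uses the morphology tags attached to utterances to pull out the tokens of
#' one category. Each token is classified by its own tag occurrence, so a
#' surface form appearing as both noun and verb contributes to both streams.
#' Utterances without tags, or whose tag vector does not align 1:1 with the
#' tokens, are skipped and counted.
#'
#' @param utterances A `chat_transcript`, its `utterances` data frame, or a
#'   list of transcripts.
#' @param tag_patterns Character vector of morphology-tier codes defining the
#'   category (e.g. one entry of [default_pos_profile()]).
#' @return Character token stream; the number of skipped utterances is
#'   attached as `attr(, "skipped")`. Errors if no utterance is tagged.
#' @export
extract_pos_tokens <- function(utterances, tag_patterns) {
  if (inherits(utterances, "chat_transcript")) {
    utterances <- utterances$utterances
  }
  if (is.list(utterances) && !is.data.frame(utterances)) {
    parts <- lapply(utterances, extract_pos_tokens,
                    tag_patterns = tag_patterns)
    out <- unlist(parts, use.names = FALSE) %||% character(0)
    attr(out, "skipped") <- sum(vapply(parts, attr, numeric(1), "skipped"))
    return(out)
  }
  stopifnot(is.data.frame(utterances))
  out <- character(0); skipped <- 0L; tagged <- 0L
  for (i in seq_len(nrow(utterances))) {
    toks <- utterances$tokens[[i]]
    tags <- utterances$mor[[i]]
    if (is.null(tags) || length(tags) != length(toks)) {
      skipped <- skipped + 1L
      next
    }
    tagged <- tagged + 1L
    out <- c(out, toks[tags %in% tag_patterns])
  }
  if (tagged == 0L) stop("no tagged utterances available for POS extraction")
  attr(out, "skipped") <- skipped
  out
}

#' Read a plain-text exclusion list
#'
#' One word form per line; blank lines and lines starting with `#` are
#' ignored. Exclusion lists are the reproducible surrogate for manual
#' cleaning of automatically extracted POS lists.
#'
#' @param file Path to the list.
#' @return Character vector of excluded word forms.
#' @export
read_exclusion_list <- function(file) {
  x <- trimws(readLines(file, encoding = "UTF-8", warn = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Remove mistagged types from a POS frequency table
#'
#' Excluded types are removed, not reassigned to another category (a word's
#' true category often cannot be determined out of context). The tagging
#' error rate is the number of excluded types divided by the number of types
#' before exclusion.
#'
#' @param table A [freq_table()] for one POS category.
#' @param excluded_types Character vector of word forms to remove. Types not
#'   present in the table are ignored with a warning.
#' @return List with `table` (the cleaned [freq_table()]) and `error_rate`
#'   in `[0, 1]`.
#' @examples
#' # 37 mistagged types out of 754:
#' round(37 / 754, 4)  # 0.0491
#' @export
apply_exclusions <- function(table, excluded_types) {
  stopifnot(inherits(table, "freq_table"))
  if (table$n_types == 0L) stop("cannot apply exclusions to an empty table")
  excluded_types <- unique(as.character(excluded_types))
  present <- excluded_types %in% names(table$counts)
  if (any(!present)) {
    warning(sum(!present), " excluded type(s) not present in the table; ignored")
  }
  n_excl <- sum(present)
  keep <- table$counts[!names(table$counts) %in% excluded_types[present]]
  new_tab <- structure(list(counts = keep,
                            total_tokens = sum(keep),
                            n_types = length(keep)),
                       class = "freq_table")
  list(table = new_tab, error_rate = n_excl / table$n_types)
}

#' Fit the ZM law to one POS token stream
#'
#' Standard ZM fitting with degeneracy detection. Streams with fewer than
#' `min_types` types are summarized but not fitted; fitted categories with
#' few types are flagged low-reliability, since exponent estimates from very
#' small type inventories (as for prepositions) are unstable.
#'
#' @param tokens Character token stream for one category.
#' @param min_types Below this number of types, no fit is attempted
#'   (default 10).
#' @param low_reliability_types Fits on fewer types than this are flagged
#'   (default 50).
#' @param tie_seed Tie-breaking seed for ranking.
#' @return A list of class `pos_fit`: `fitted` flag, the summary columns of
#'   [summarize_table()], and when fitted `alpha`, `beta`, `pearson_r`,
#'   `degenerate`, `low_reliability`.
#' @export
fit_pos <- function(tokens, min_types = 10L, low_reliability_types = 50L,
                    tie_seed = 0L) {
  tab <- build_table(tokens)
  if (tab$n_types == 0L) stop("empty POS token stream")
  sm <- summarize_table(tab)
  out <- c(list(fitted = FALSE), sm,
           list(alpha = NA_real_, beta = NA_real_, pearson_r = NA_real_,
                degenerate = NA, low_reliability = tab$n_types <
                  low_reliability_types))
  if (tab$n_types >= min_types) {
    fit <- fit_zm(assign_ranks(tab, tie_seed = tie_seed))
    out$fitted <- TRUE
    out$alpha <- fit$alpha; out$beta <- fit$beta
    out$pearson_r <- fit$pearson_linear
    out$degenerate <- fit$degenerate
  }
  structure(out, class = "pos_fit")
}

#' @export
print.pos_fit <- function(x, digits = 4, ...) {
  cat("POS fit: ", x$n_types, " types, ", format(x$n_tokens, big.mark = ","),
      " tokens", if (x$low_reliability) " [low reliability]", "\n", sep = "")
  if (x$fitted) {
    cat("  alpha = ", format(x$alpha, digits = digits),
        ", beta = ", format(x$beta, digits = digits),
        if (isTRUE(x$degenerate)) ", degenerate (no correlation)"
        else paste0(", Pearson r = ", format(x$pearson_r, digits = digits)),
        "\n", sep = "")
  } else {
    cat("  too few types: summarized only\n")
  }
  invisible(x)
}
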