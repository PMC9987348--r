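#' Word-frequency table
#'
#' Container for a word -> count association. Counts may be fractional, to
#' accommodate frequency lists distributed as relative frequencies (which can
#' yield non-integer token totals).
#'
#' @param words Character vector of word forms.
#' @param counts Numeric vector of positive counts, same length as `words`.
#' @return An object of class `freq_table`: list with `counts` (named numeric),
#'   `total_tokens` and `n_types`.
#' @examples
#' ft <- freq_table(c("a", "b"), c(5, 3))
#' ft$total_tokens  # 8
#' @export
freq_table <- function(words, counts) {
  stopifnot(length(words) == length(counts))
  words <- as.character(words)
  counts <- as.numeric(counts)
  bad <- !is.finite(counts) | counts <= 0
  if (any(bad)) {
    warning(sum(bad), " row(s) with non-positive count rejected")
    words <- words[!bad]; counts <- counts[!bad]
  }
  if (anyDuplicated(words)) {
    warning("duplicate word form(s) merged by summing counts")
    counts <- tapply(counts, words, sum)
    words <- names(counts)
    counts <- as.numeric(counts)
  }
  names(counts) <- words
  structure(list(counts = counts,
                 total_tokens = sum(counts),
                 n_types = length(counts)),
            class = "freq_table")
}

#' @export
print.freq_table <- function(x, ...) {
  cat("Word frequency table:", x$n_types, "types,",
      format(x$total_tokens, big.mark = ","), "tokens\n")
  invisible(x)
}

#' Count word frequencies in a token stream
#'
#' @param tokens Character vector of word tokens.
#' @return A [freq_table()]; empty input yields an empty table with total 0.
#' @examples
#' build_table(c("a", "b", "a"))
#' @export
build_table <- function(tokens) {
  if (!length(tokens)) {
    return(structure(list(counts = stats::setNames(numeric(0), character(0)),
                          total_tokens = 0L, n_types = 0L),
                     class = "freq_table"))
  }
  tb <- table(tokens)
  structure(list(counts = stats::setNames(as.numeric(tb), names(tb)),
                 total_tokens = length(tokens),
                 n_types = length(tb)),
            class = "freq_table")
}

#' Rank words by frequency, breaking ties at random
#'
#' The most frequent word receives rank 1. Words sharing a count occupy a
#' block of consecutive ranks in an order given by a uniform random
#' permutation driven by `tie_seed`; the rank -> frequency mapping itself is
#' identical for every seed, so fitted parameters do not depend on it.
#'
#' @param table A non-empty [freq_table()].
#' @param tie_seed Integer RNG seed for tie-breaking; recorded in the result.
#' @return An object of class `ranked_dist`: list with `words`, `frequencies`
#'   (non-increasing), `tie_seed`, `total_tokens`, `n_types`.
#' @export
assign_ranks <- function(table, tie_seed = 0L) {
  stopifnot(inherits(table, "freq_table"))
  if (table$n_types == 0L) stop("cannot rank an empty frequency table")
  n <- table$n_types
  tie_break <- with_seed(tie_seed, sample.int(n))
  ord <- order(-table$counts, tie_break)
  structure(list(words = names(table$counts)[ord],
                 frequencies = unname(table$counts[ord]),
                 tie_seed = as.integer(tie_seed),
                 total_tokens = table$total_tokens,
                 n_types = n),
            class = "ranked_dist")
}

#' @export
print.ranked_dist <- function(x, ...) {
  cat("Ranked distribution:", x$n_types, "types,",
      format(x$total_tokens, big.mark = ","), "tokens (tie seed ",
      x$tie_seed, ")\n", sep = " ")
  invisible(x)
}

#' Frequency per million tokens
#'
#' @param count Raw count(s).
#' @param total_tokens Corpus size in tokens; must be positive.
#' @return `1e6 * count / total_tokens`, rounded to two decimals.
#' @examples
#' per_million(303005, 6311249)  # 48010.31
#' @export
per_million <- function(count, total_tokens) {
  if (!is.finite(total_tokens) || total_tokens <= 0) {
    stop("total_tokens must be positive")
  }
  round(1e6 * count / total_tokens, 2)
}

#' Summary statistics of a frequency table
#'
#' The column set used in corpus summary tables: tokens, types, the raw
#' frequency range and the per-million frequency range.
#'
#' @param table A non-empty [freq_table()].
#' @return A list with `n_tokens`, `n_types`, `min_count`, `max_count`,
#'   `min_per_million`, `max_per_million`.
#' @export
summarize_table <- function(table) {
  stopifnot(inherits(table, "freq_table"))
  if (table$n_types == 0L) stop("cannot summarize an empty frequency table")
  cnt <- table$counts
  list(n_tokens = table$total_tokens,
       n_types = table$n_types,
       min_count = min(cnt),
       max_count = max(cnt),
       min_per_million = per_million(min(cnt), table$total_tokens),
       max_per_million = per_million(max(cnt), table$total_tokens))
}

#' Write a ranked distribution as CSV
#'
#' @param ranked A `ranked_dist`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ranked_csv <- function(ranked, path) {
  df <- data.frame(rank = seq_along(ranked$frequencies),
                   word = ranked$words,
                   count = ranked$frequencies,
                   per_million = per_million(ranked$frequencies,
                                             ranked$total_tokens))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
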