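#' Selection rules for assembling a child-directed-speech corpus
#'
#' Bundles the filtering conventions used throughout the pipeline: the maximum
#' child age at recording, which speaker roles are removed as non-adult input,
#' and the minimum corpus size (in tokens) below which a language is excluded
#' from whole-corpus fitting.
#'
#' @param max_child_age_months Upper bound (inclusive) on the target child's
#'   age at recording, in months. Default 42 (3;6).
#' @param child_roles Speaker roles always removed as child speech.
#' @param exclude_young If `TRUE` (default), roles typically held by other
#'   young interlocutors (siblings, playmates, ...) are removed as well; the
#'   retained input then comes from caregivers and investigators only.
#' @param min_corpus_tokens Minimum number of adult tokens a corpus must
#'   contribute to be analysed as a whole. Default 100000.
#' @return An object of class `corpus_selection`.
#' @examples
#' sel <- corpus_selection()
#' sel$adult_roles_excluded
#' @export
corpus_selection <- function(max_child_age_months = 42L,
                             child_roles = c("Target_Child", "Child"),
                             exclude_young = TRUE,
                             min_corpus_tokens = 100000L) {
  stopifnot(min_corpus_tokens > 0, max_child_age_months >= 0)
  young <- c("Sibling", "Brother", "Sister", "Playmate", "Cousin",
             "Boy", "Girl", "Baby", "Twin")
  structure(
    list(max_child_age_months = as.integer(max_child_age_months),
         adult_roles_excluded = if (exclude_young) c(child_roles, young)
                                else child_roles,
         min_corpus_tokens = as.integer(min_corpus_tokens)),
    class = "corpus_selection")
}

#' Convert a CHAT age string to months
#'
#' CHAT encodes ages as `Y;M` or `Y;M.D` (years;months.days). Days are
#' dropped; the result is `12 * Y + M` months. Empty or missing input yields
#' `NA`.
#'
#' @param age_text Character vector of CHAT age strings.
#' @return Integer vector of ages in months (`NA` where input was empty).
#' @examples
#' parse_age("0;11")   # 11
#' parse_age("2;3.15") # 27
#' parse_age("3;6")    # 42
#' @export
parse_age <- function(age_text) {
  out <- rep(NA_integer_, length(age_text))
  blank <- is.na(age_text) | !nzchar(trimws(age_text))
  todo <- which(!blank)
  if (!length(todo)) return(out)
  m <- regmatches(age_text[todo],
                  regexec("^\\s*([0-9]+);([0-9]+)(\\.([0-9]*))?\\s*$",
                          age_text[todo]))
  bad <- vapply(m, function(x) length(x) == 0L, logical(1))
  if (any(bad)) {
    stop("unparseable age value(s): ",
         paste(sQuote(age_text[todo][bad]), collapse = ", "))
  }
  out[todo] <- vapply(m, function(x) {
    12L * as.integer(x[2]) + as.integer(x[3])
  }, integer(1))
  out
}

#' Clean a CHAT main-tier line into orthographic word forms
#'
#' Removes transcriber annotation so that only orthographic word forms remain:
#' bracketed material (comments, corrections, repetition markers such as
#' `[x 3]`), angle-bracket scoping, event and filler codes beginning with `&`,
#' unintelligible-speech codes (`xxx`, `yyy`, `www`), omitted-word codes
#' beginning with `0`, special-form `@` suffixes, utterance terminators and
#' other punctuation-only tokens. A word is its surface orthographic string;
#' clitic and compound joiners (`+`, `_`) inside a word are kept.
#'
#' @param main_tier_text Character vector of raw main-tier strings.
#' @param lowercase Fold case before counting (default `TRUE`); CHAT
#'   capitalises sentence-initial words, which would otherwise split one type
#'   into two.
#' @return Character vector of cleaned word forms (possibly empty).
#' @examples
#' clean_tokens("&=laughs xxx doggy .")     # "doggy"
#' clean_tokens("where is the bunny ?")     # "where" "is" "the" "bunny"
#' clean_tokens("dog [= the toy] !")        # "dog"
#' @export
clean_tokens <- function(main_tier_text, lowercase = TRUE) {
  x <- paste(main_tier_text, collapse = " ")
  # bracketed annotations, innermost first in case of nesting
  repeat {
    x2 <- gsub("\\[[^][]*\\]", " ", x)
    if (identical(x2, x)) break
    x <- x2
  }
  x <- gsub("[<>]", " ", x)      # retrace scoping: keep the words inside
  x <- gsub("[()]", "", x)       # shortenings: "(be)cause" -> "because"
  toks <- strsplit(x, "[[:space:]]+")[[1]]
  toks <- toks[nzchar(toks)]
  toks <- toks[!grepl("^[&+]", toks)]                 # events, fillers, +codes
  toks <- toks[!toks %in% c("xxx", "yyy", "www")]     # unintelligible
  toks <- toks[!grepl("^0", toks)]                    # omitted words
  toks <- sub("@.*$", "", toks)                       # special-form suffixes
  toks <- gsub("^[\"“”‘’«»]+|[\"“”‘’«»,.!?;:]+$",
               "", toks)
  toks <- toks[nzchar(toks)]
  toks <- toks[!grepl("^[[:punct:]]+$", toks)]        # terminators etc.
  toks <- toks[!grepl("[][<>&%*\"[:space:]]", toks)]  # residual markup
  if (lowercase) toks <- tolower(toks)
  toks
}

# Parse one %mor word into its category code (the part before the first "|").
mor_tag <- function(mor_word) sub("\\|.*$", "", mor_word)

#' Parse a CHAT transcript
#'
#' Reads a CHAT (`.cha`) file: `@` header lines, `*` main speaker tiers and
#' `%` dependent tiers. Speaker roles are resolved from `@ID` headers (with
#' `@Participants` as fallback); the target child's age is taken from their
#' `@ID` record. `%mor` tiers, when present and alignable, are attached as
#' per-token category tags.
#'
#' @param file Path to a CHAT file (UTF-8).
#' @param text Alternatively, the transcript content as a character vector of
#'   lines (used instead of `file`).
#' @param lowercase Passed to [clean_tokens()].
#' @param ordering_key Sort key used for conversationally continuous sampling;
#'   defaults to the file path.
#' @return An object of class `chat_transcript`: a list with `meta` (path,
#'   corpus name, language, `child_age_months`, ordering key) and
#'   `utterances`, a data frame with columns `speaker`, `role`, and
#'   list-columns `tokens` and `mor` (tag vector or `NULL`).
#' @seealso [filter_adult()], [read_chat_corpus()]
#' @export
parse_chat <- function(file = NULL, text = NULL, lowercase = TRUE,
                       ordering_key = NULL) {
  if (is.null(text)) {
    stopifnot(!is.null(file))
    lines <- readLines(file, encoding = "UTF-8", warn = FALSE)
    path <- as.character(file)
  } else {
    lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
    path <- file %||% "<text>"
  }
  # continuation lines (leading tab/space) belong to the previous tier
  if (length(lines)) {
    cont <- grepl("^[\t ]", lines) & !grepl("^[@*%]", lines)
    cont[1] <- FALSE
    if (any(cont)) {
      grp <- cumsum(!cont)
      lines <- unname(vapply(split(sub("^[\t ]+", " ", lines), grp),
                             paste, character(1), collapse = ""))
    }
  }

  split_tier <- function(l) {
    code <- sub("^([@*%])([^:]*):?.*$", "\\2", l)
    body <- sub("^[@*%][^:]*:[\t ]*", "", l)
    c(code, body)
  }

  roles <- character(0)     # speaker code -> role
  langs <- character(0)
  corpus_name <- NA_character_
  child_age <- NA_integer_

  id_lines <- grep("^@ID", lines, value = TRUE)
  for (l in id_lines) {
    body <- split_tier(l)[2]
    f <- strsplit(body, "|", fixed = TRUE)[[1]]
    if (length(f) < 8) {
      warning("malformed @ID header: ", l)
      next
    }
    code <- trimws(f[3]); role <- trimws(f[8])
    roles[code] <- role
    if (is.na(corpus_name)) corpus_name <- trimws(f[2])
    if (!length(langs)) langs <- trimws(f[1])
    if (identical(role, "Target_Child") || identical(code, "CHI")) {
      age <- tryCatch(parse_age(trimws(f[4])), error = function(e) {
        warning("malformed age in @ID header: ", conditionMessage(e))
        NA_integer_
      })
      if (is.na(child_age)) child_age <- age
    }
  }
  # @Participants fallback: "CHI Jane Target_Child, MOT Mary Mother"
  pt <- grep("^@Participants", lines, value = TRUE)
  if (length(pt)) {
    for (part in strsplit(split_tier(pt[1])[2], ",", fixed = TRUE)[[1]]) {
      w <- strsplit(trimws(part), "[[:space:]]+")[[1]]
      if (length(w) >= 2) {
        code <- w[1]
        if (!code %in% names(roles) || !nzchar(roles[code])) {
          roles[code] <- w[length(w)]
        }
      }
    }
  }

  is_main <- grepl("^\\*", lines)
  is_dep <- grepl("^%", lines)
  speakers <- character(0); tok_list <- list(); mor_list <- list()
  idx <- 0L
  for (i in seq_along(lines)) {
    if (is_main[i]) {
      st <- split_tier(lines[i])
      idx <- idx + 1L
      speakers[idx] <- st[1]
      tok_list[[idx]] <- clean_tokens(st[2], lowercase = lowercase)
      mor_list[idx] <- list(NULL)
    } else if (is_dep[i] && idx > 0L) {
      st <- split_tier(lines[i])
      if (identical(st[1], "mor")) {
        mw <- strsplit(trimws(st[2]), "[[:space:]]+")[[1]]
        mw <- mw[nzchar(mw) & !grepl("^[[:punct:]]+$", mw)]
        if (length(mw)) mor_list[[idx]] <- mor_tag(mw)
      }
    }
  }
  if (idx == 0L) warning("no main tiers found in ", path)

  utt <- data.frame(
    speaker = if (idx) speakers else character(0),
    role = if (idx) unname(ifelse(speakers %in% names(roles),
                                  roles[speakers], NA_character_))
           else character(0),
    stringsAsFactors = FALSE)
  utt$tokens <- tok_list
  utt$mor <- mor_list

  meta <- list(path = path,
               corpus_name = corpus_name,
               language = if (length(langs)) langs else NA_character_,
               child_age_months = child_age,
               ordering_key = ordering_key %||% path)
  structure(list(meta = meta, utterances = utt), class = "chat_transcript")
}

#' @export
print.chat_transcript <- function(x, ...) {
  cat("CHAT transcript:", x$meta$path, "\n",
      " corpus:", x$meta$corpus_name,
      " language:", x$meta$language,
      " child age (months):", x$meta$child_age_months, "\n",
      " utterances:", nrow(x$utterances), "\n")
  invisible(x)
}

#' Keep only adult utterances
#'
#' Removes utterances produced by the child (and, by default, by other young
#' interlocutors), retaining caregivers and investigators. Utterances with an
#' unknown role are conservatively kept.
#'
#' @param x A `chat_transcript` or its `utterances` data frame.
#' @param selection A [corpus_selection()].
#' @return Same type as `x`, with non-adult utterances removed. Idempotent.
#' @export
filter_adult <- function(x, selection = corpus_selection()) {
  if (inherits(x, "chat_transcript")) {
    x$utterances <- filter_adult(x$utterances, selection)
    return(x)
  }
  stopifnot(is.data.frame(x))
  if (!nrow(x)) return(x)
  unknown <- is.na(x$role) | !nzchar(x$role)
  if (any(unknown)) {
    message(sum(unknown), " utterance(s) with unknown speaker role kept")
  }
  keep <- unknown | !(x$role %in% selection$adult_roles_excluded)
  x[keep, , drop = FALSE]
}

#' Read a precomputed word-frequency list
#'
#' Reads a two-column table of word and count (or relative frequency; counts
#' need not be integers, so fractional totals are permitted). Duplicate words
#' are merged by summing, with a warning; rows with non-positive counts are
#' rejected, with a warning.
#'
#' @param file Path to a CSV or TSV file. The separator is sniffed from the
#'   first line (tab if present, comma otherwise) unless given.
#' @param sep Field separator; `NULL` (default) to sniff.
#' @param header Does the file carry a header row? `NA` (default) to sniff:
#'   a non-numeric second field on line one is treated as a header.
#' @return A [freq_table()].
#' @export
read_frequency_list <- function(file, sep = NULL, header = NA) {
  first <- readLines(file, n = 1L, encoding = "UTF-8")
  if (is.null(sep)) sep <- if (grepl("\t", first)) "\t" else ","
  if (is.na(header)) {
    f2 <- strsplit(first, sep, fixed = TRUE)[[1]]
    header <- length(f2) >= 2 && is.na(suppressWarnings(as.numeric(f2[2])))
  }
  df <- utils::read.table(file, sep = sep, header = header,
                          stringsAsFactors = FALSE, quote = "\"",
                          fileEncoding = "UTF-8")
  stopifnot(ncol(df) >= 2)
  freq_table(as.character(df[[1]]), as.numeric(df[[2]]))
}

#' Read a directory or set of CHAT files
#'
#' @param x A directory containing `.cha` files, or a character vector of
#'   file paths.
#' @param ... Passed to [parse_chat()].
#' @return A list of `chat_transcript` objects, ordered by
#'   (corpus name, path) — the default ordering used for conversationally
#'   continuous sampling.
#' @export
read_chat_corpus <- function(x, ...) {
  files <- if (length(x) == 1L && dir.exists(x)) {
    list.files(x, pattern = "\\.cha$", full.names = TRUE)
  } else x
  ts <- lapply(files, function(f) parse_chat(file = f, ...))
  ord <- order(vapply(ts, function(t) t$meta$corpus_name %||% "", character(1)),
               vapply(ts, function(t) t$meta$path, character(1)))
  ts[ord]
}

#' Write a cleaned token stream with sidecar metadata
#'
#' Writes one utterance per line (space-separated tokens) as UTF-8 text, and a
#' JSON sidecar (`<path>.json`) with the transcript metadata.
#'
#' @param utterance_tokens List of character vectors, one utterance each.
#' @param meta Transcript metadata list (as in `chat_transcript$meta`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tokens <- function(utterance_tokens, meta, path) {
  writeLines(vapply(utterance_tokens, paste, character(1), collapse = " "),
             path, useBytes = TRUE)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}
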