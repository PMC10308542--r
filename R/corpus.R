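#' Read a corpus of posts from JSONL or CSV
#'
#' Ingests sentence-classification input: one record per post with the fields
#' \code{post_id}, \code{author_id}, \code{text}, \code{posted_at} and
#' \code{condition}. Timestamps are parsed as ISO-8601 (date or date-time) or
#' epoch seconds; timezone-naive values are treated as UTC. Text is Unicode
#' NFC-normalised. Posts whose text is empty after whitespace normalisation
#' are dropped with a message (their count is recorded in the
#' \code{"n_dropped_empty"} attribute).
#'
#' @param path Path to the input file.
#' @param format Either \code{"jsonl"} (one JSON object per line, UTF-8) or
#'   \code{"csv"} (header row required).
#' @param strict If \code{TRUE}, malformed records (missing \code{post_id} or
#'   \code{text}) are an error; if \code{FALSE} (default) they are skipped
#'   with a warning naming the offending line numbers.
#' @return A data frame of posts with columns \code{post_id},
#'   \code{author_id}, \code{text}, \code{posted_at} (\code{POSIXct}, UTC;
#'   \code{NA} when absent) and \code{condition} (one of
#'   \code{"mental_health"}, \code{"control"}, \code{"unlabeled"}).
#' @export
read_corpus <- function(path, format = c("jsonl", "csv"), strict = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "jsonl") {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    recs <- lapply(lines, function(l) {
      tryCatch(jsonlite::fromJSON(l), error = function(e) NULL)
    })
    bad_parse <- vapply(recs, is.null, logical(1))
    if (any(bad_parse)) {
      msg <- paste0("unparseable JSONL record(s) at line(s): ",
                    paste(which(bad_parse), collapse = ", "))
      if (strict) stop(msg) else warning(msg)
    }
    df <- do.call(rbind, lapply(which(!bad_parse), function(i) {
      r <- recs[[i]]
      data.frame(
        line = i,
        post_id = as.character(r$post_id %||% NA_character_),
        author_id = as.character(r$author_id %||% NA_character_),
        text = as.character(r$text %||% NA_character_),
        posted_at_raw = as.character(r$posted_at %||% NA_character_),
        condition = as.character(r$condition %||% "unlabeled"),
        stringsAsFactors = FALSE
      )
    }))
    if (is.null(df)) df <- data.frame(line = integer(), post_id = character(),
                                      author_id = character(), text = character(),
                                      posted_at_raw = character(),
                                      condition = character())
  } else {
    raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = "character", encoding = "UTF-8")
    need <- c("post_id", "author_id", "text", "posted_at", "condition")
    for (f in setdiff(need, names(raw))) raw[[f]] <- NA_character_
    df <- data.frame(
      line = seq_len(nrow(raw)) + 1L,  # header is line 1
      post_id = raw$post_id, author_id = raw$author_id, text = raw$text,
      posted_at_raw = raw$posted_at,
      condition = ifelse(is.na(raw$condition) | raw$condition == "",
                         "unlabeled", raw$condition),
      stringsAsFactors = FALSE
    )
  }

  malformed <- is.na(df$post_id) | df$post_id == "" | is.na(df$text)
  if (any(malformed)) {
    msg <- paste0("record(s) missing post_id or text at line(s): ",
                  paste(df$line[malformed], collapse = ", "))
    if (strict) stop(msg)
    warning(msg, "; skipped")
    df <- df[!malformed, , drop = FALSE]
  }
  if (anyDuplicated(df$post_id)) stop("duplicate post_id in corpus")

  df$text <- normalize_text(df$text)
  empty <- !nzchar(trimws(df$text))
  n_dropped <- sum(empty)
  if (n_dropped > 0) {
    message(n_dropped, " post(s) empty after whitespace normalization; dropped")
    df <- df[!empty, , drop = FALSE]
  }

  ok_cond <- c("mental_health", "control", "unlabeled")
  bad_cond <- !(df$condition %in% ok_cond)
  if (any(bad_cond)) {
    warning("unknown condition label(s) set to 'unlabeled': ",
            paste(unique(df$condition[bad_cond]), collapse = ", "))
    df$condition[bad_cond] <- "unlabeled"
  }

  posts <- data.frame(
    post_id = df$post_id, author_id = df$author_id, text = df$text,
    posted_at = parse_timestamp(df$posted_at_raw),
    condition = df$condition, stringsAsFactors = FALSE
  )
  rownames(posts) <- NULL
  attr(posts, "n_dropped_empty") <- n_dropped
  class(posts) <- c("ftr_corpus", "data.frame")
  posts
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

normalize_text <- function(x) {
  x <- enc2utf8(as.character(x))
  x <- stringi_nfc(x)
  gsub("[ \t\r\n]+", " ", x)
}

# NFC normalisation without a hard stringi dependency; iconv round-trip is a
# no-op for already-composed text and base R lacks a composer, so fall back to
# identity when icu is unavailable. Inputs from the shipped generators are NFC.
stringi_nfc <- function(x) {
  if (requireNamespace("stringi", quietly = TRUE)) {
    return(stringi::stri_trans_nfc(x))
  }
  x
}

#' Parse posting timestamps
#'
#' Accepts ISO-8601 dates (\code{"2020-06-10"}), date-times
#' (\code{"2020-06-10T16:00:00"}, with optional \code{Z} or numeric offset)
#' and epoch seconds. Timezone-naive values are interpreted as UTC.
#'
#' @param x Character vector of raw timestamp strings (or numbers).
#' @return \code{POSIXct} vector in UTC; \code{NA} where unparseable.
#' @export
parse_timestamp <- function(x) {
  x <- as.character(x)
  out <- rep(as.POSIXct(NA), length(x))
  attr(out, "tzone") <- "UTC"
  for (i in seq_along(x)) {
    s <- trimws(x[i])
    if (is.na(s) || !nzchar(s)) next
    if (grepl("^-?[0-9]+(\\.[0-9]+)?$", s) && !grepl("^[0-9]{4}-", s)) {
      out[i] <- as.POSIXct(as.numeric(s), origin = "1970-01-01", tz = "UTC")
      next
    }
    s2 <- sub("Z$", "", sub("T", " ", s))
    fmt <- c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M", "%Y-%m-%d")
    for (f in fmt) {
      v <- as.POSIXct(s2, format = f, tz = "UTC")
      if (!is.na(v)) { out[i] <- v; break }
    }
  }
  out
}

# Abbreviations that a terminal period does not end a sentence after.
.abbreviations <- c(
  "mr", "mrs", "ms", "dr", "prof", "st", "jr", "sr", "vs", "etc", "approx",
  "e.g", "i.e", "cf", "al", "no", "fig", "inc", "ltd", "co", "dept", "est",
  "jan", "feb", "mar", "apr", "jun", "jul", "aug", "sep", "sept", "oct",
  "nov", "dec"
)

#' Split a post into sentences
#'
#' Rule-based sentence boundary detection: sentences end at runs of
#' \code{. ! ?} followed by whitespace and an upper-case letter, digit or
#' opening quote, except after a known abbreviation ("e.g.", "Dr.", ...) or a
#' single-letter initial. Deterministic: identical text always yields
#' identical spans. Whitespace-only text yields zero sentences.
#'
#' @param text Post text (single string), or a post data frame row from
#'   \code{\link{read_corpus}}.
#' @param post_id Identifier copied onto the output rows.
#' @return Data frame with columns \code{post_ref}, \code{sent_index}
#'   (0-based), \code{text}, \code{start}, \code{end} (half-open character
#'   offsets into the input). The \code{"segmenter"} attribute names the
#'   backend that ran.
#' @export
split_sentences <- function(text, post_id = NA_character_) {
  if (is.data.frame(text)) {
    stopifnot(nrow(text) == 1L)
    post_id <- text$post_id
    text <- text$text
  }
  stopifnot(is.character(text), length(text) == 1L)
  empty <- data.frame(post_ref = character(), sent_index = integer(),
                      text = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  attr(empty, "segmenter") <- "rule_based"
  if (is.na(text) || !nzchar(trimws(text))) return(empty)

  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  boundaries <- integer(0)
  i <- 1L
  while (i <= n) {
    if (chars[i] %in% c(".", "!", "?")) {
      j <- i
      while (j < n && chars[j + 1L] %in% c(".", "!", "?", "\"", "'", ")")) j <- j + 1L
      # look back for abbreviation / initial (periods only)
      is_abbrev <- FALSE
      if (chars[i] == ".") {
        k <- i - 1L
        while (k >= 1L && grepl("[A-Za-z.]", chars[k])) k <- k - 1L
        word <- tolower(paste(chars[(k + 1L):(i - 1L)], collapse = ""))
        word <- sub("\\.$", "", word)
        if (word %in% .abbreviations || grepl("^[a-z]$", word) ||
            grepl("^([a-z]\\.)+[a-z]?$", word)) {
          is_abbrev <- TRUE
        }
      }
      # boundary only if followed by whitespace + sentence-initial char, or EOT
      nxt <- j + 1L
      while (nxt <= n && chars[nxt] == " ") nxt <- nxt + 1L
      starts_new <- nxt > n ||
        (nxt > j + 1L && grepl("[A-Z0-9\"'(]", chars[nxt]))
      if (!is_abbrev && starts_new) boundaries <- c(boundaries, j)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  ends <- unique(c(boundaries, n))
  starts <- c(1L, head(ends, -1L) + 1L)
  out <- list()
  idx <- 0L
  for (s in seq_along(starts)) {
    a <- starts[s]; b <- ends[s]
    # trim leading/trailing spaces but keep offsets honest
    while (a <= b && chars[a] == " ") a <- a + 1L
    while (b >= a && chars[b] == " ") b <- b - 1L
    if (a > b) next
    seg <- paste(chars[a:b], collapse = "")
    out[[length(out) + 1L]] <- data.frame(
      post_ref = post_id, sent_index = idx, text = seg,
      start = a - 1L, end = b, stringsAsFactors = FALSE)
    idx <- idx + 1L
  }
  res <- if (length(out)) do.call(rbind, out) else empty
  attr(res, "segmenter") <- "rule_based"
  res
}

#' Segment every post in a corpus
#'
#' @param posts Data frame from \code{\link{read_corpus}} (or with the same
#'   columns).
#' @return Data frame of sentences carrying \code{post_ref},
#'   \code{sent_index}, \code{text}, \code{start}, \code{end}, plus the
#'   post's \code{posted_at} and \code{condition} for downstream stages.
#' @export
segment_corpus <- function(posts) {
  pieces <- lapply(seq_len(nrow(posts)), function(i) {
    s <- split_sentences(posts$text[i], posts$post_id[i])
    if (nrow(s) == 0) return(NULL)
    s$posted_at <- posts$posted_at[i]
    s$condition <- posts$condition[i]
    s
  })
  out <- do.call(rbind, pieces)
  if (is.null(out)) {
    out <- data.frame(post_ref = character(), sent_index = integer(),
                      text = character(), start = integer(), end = integer(),
                      posted_at = as.POSIXct(character(), tz = "UTC"),
                      condition = character(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "segmenter") <- "rule_based"
  out
}
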