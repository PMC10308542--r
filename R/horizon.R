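# Rule-based temporal expression tagging and the sentence time-horizon
# statistic H(s): the mean signed day-distance between a sentence's resolved
# temporal references and its posting time.

.weekdays <- c(sunday = 0L, monday = 1L, tuesday = 2L, wednesday = 3L,
               thursday = 4L, friday = 5L, saturday = 6L)
.months <- stats::setNames(1:12, tolower(month.name))
.month_abbr <- stats::setNames(1:12, tolower(month.abb))
.numwords <- c(a = 1, an = 1, one = 1, two = 2, three = 3, four = 4,
               five = 5, six = 6, seven = 7, eight = 8, nine = 9, ten = 10,
               eleven = 11, twelve = 12)

parse_count <- function(s) {
  s <- tolower(trimws(s))
  if (grepl("^[0-9]+$", s)) return(as.numeric(s))
  v <- .numwords[s]
  if (is.na(v)) NA_real_ else as.numeric(v)
}

month_shift <- function(date, k) {
  seq(date, by = paste(k, "month"), length.out = 2)[2]
}
year_shift <- function(date, k) {
  seq(date, by = paste(k, "year"), length.out = 2)[2]
}

unit_shift <- function(date, n, unit) {
  unit <- sub("s$", "", tolower(unit))
  switch(unit,
         hour = date,                        # sub-day: same calendar date
         minute = date,
         day = date + n,
         week = date + 7 * n,
         month = month_shift(date, n),
         year = year_shift(date, n),
         NULL)
}

anchor_date <- function(anchor) {
  if (inherits(anchor, "Date")) return(anchor)
  as.Date(anchor, tz = "UTC")
}

# Find all matches of `pattern` in `text`; returns start/end (1-based,
# inclusive) and the match surface plus capture groups.
find_matches <- function(text, pattern) {
  m <- gregexpr(pattern, text, ignore.case = TRUE, perl = TRUE)[[1]]
  if (m[1] == -1) return(NULL)
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  surfaces <- substring(text, starts, starts + lens - 1L)
  groups <- lapply(surfaces, function(s) {
    r <- regexec(pattern, s, ignore.case = TRUE, perl = TRUE)[[1]]
    gs <- substring(s, as.integer(r), as.integer(r) + attr(r, "match.length") - 1L)
    gs[-1]
  })
  list(start = starts, end = starts + lens - 1L, surface = surfaces,
       groups = groups)
}

.time_suffix <- "(?:\\s+at\\s+[0-9]{1,2}(?::[0-9]{2})?\\s*(?:am|pm)?)?"

#' Extract and resolve temporal expressions
#'
#' Scans a sentence with a deterministic rule inventory — keyword deictics
#' (today/tonight/tomorrow/yesterday, day after tomorrow), "in N units",
#' "N units ago", next/last/this + week/month/year, weekday names with
#' this/next/last, month-name dates ("November 7, 2012"), numeric dates
#' (day-first by default) and ISO dates — and resolves each match to a
#' calendar date relative to the anchor (posting) timestamp. Matching is
#' greedy in priority order (absolute patterns first) and claimed character
#' spans are never re-matched, so no two expressions share a span.
#' Sub-day expressions ("tonight", "in two hours") resolve to the anchor
#' date itself.
#'
#' @param text Sentence text (single string).
#' @param anchor Posting timestamp (\code{POSIXct} or \code{Date}); required.
#' @param dayfirst Parse numeric dates like \code{10-06-2020} as
#'   day-month-year (default \code{TRUE}); set \code{FALSE} for
#'   month-day-year input.
#' @return Data frame with columns \code{surface}, \code{start}, \code{end}
#'   (character offsets), \code{kind} (\code{"absolute"}, \code{"relative"}
#'   or \code{"combined"}), \code{resolved} (\code{Date}) and \code{sub_day}
#'   (logical: resolved only to within the anchor day).
#' @export
extract_temporal_expressions <- function(text, anchor, dayfirst = TRUE) {
  if (missing(anchor) || is.null(anchor) || (length(anchor) == 1 && is.na(anchor)))
    stop("anchor timestamp is required to resolve temporal expressions")
  ad <- anchor_date(anchor)
  stopifnot(is.character(text), length(text) == 1L)

  claimed <- rep(FALSE, nchar(text))
  rows <- list()
  add <- function(start, end, surface, kind, resolved, sub_day = FALSE) {
    span <- start:end
    if (any(claimed[span])) return(invisible(NULL))
    if (is.null(resolved) || is.na(resolved)) {
      message("unparseable temporal candidate skipped: ", surface)
      return(invisible(NULL))
    }
    claimed[span] <<- TRUE
    rows[[length(rows) + 1L]] <<- data.frame(
      surface = surface, start = start, end = end, kind = kind,
      resolved = resolved, sub_day = sub_day, stringsAsFactors = FALSE)
    invisible(NULL)
  }
  scan <- function(pattern, handler, kind) {
    fm <- find_matches(text, pattern)
    if (is.null(fm)) return(invisible(NULL))
    for (i in seq_along(fm$start)) {
      h <- handler(fm$groups[[i]], fm$surface[i])
      add(fm$start[i], fm$end[i], fm$surface[i],
          if (is.function(kind)) kind(fm$surface[i]) else kind,
          h$date, isTRUE(h$sub_day))
    }
  }
  rel_kind <- function(surface) {
    if (grepl("\\bat\\b", surface, ignore.case = TRUE)) "combined" else "relative"
  }

  # -- absolute dates ---------------------------------------------------------
  scan("\\b([0-9]{4})-([0-9]{2})-([0-9]{2})\\b", function(g, s) {
    list(date = as.Date(sprintf("%s-%s-%s", g[1], g[2], g[3])))
  }, "absolute")
  mn <- paste(c(tolower(month.name), tolower(month.abb)), collapse = "|")
  scan(sprintf("\\b(%s)\\.?\\s+([0-9]{1,2})(?:st|nd|rd|th)?\\s*,?\\s+([0-9]{4})\\b", mn),
       function(g, s) {
         m <- .months[tolower(g[1])]
         if (is.na(m)) m <- .month_abbr[tolower(g[1])]
         list(date = as.Date(sprintf("%s-%02d-%02d", g[3], m, as.integer(g[2]))))
       }, "absolute")
  scan(sprintf("\\b([0-9]{1,2})(?:st|nd|rd|th)?\\s+(%s)\\.?\\s+([0-9]{4})\\b", mn),
       function(g, s) {
         m <- .months[tolower(g[2])]
         if (is.na(m)) m <- .month_abbr[tolower(g[2])]
         list(date = as.Date(sprintf("%s-%02d-%02d", g[3], m, as.integer(g[1]))))
       }, "absolute")
  scan("\\b([0-9]{1,2})[-/]([0-9]{1,2})[-/]([0-9]{2,4})\\b", function(g, s) {
    d <- as.integer(g[1]); m <- as.integer(g[2]); y <- as.integer(g[3])
    if (!dayfirst) { tmp <- d; d <- m; m <- tmp }
    if (y < 100) y <- y + 2000L
    if (m > 12 || d > 31) return(list(date = as.Date(NA)))
    list(date = as.Date(sprintf("%04d-%02d-%02d", y, m, d)))
  }, "absolute")

  # -- relative ---------------------------------------------------------------
  scan(paste0("\\bday\\s+after\\s+tomorrow\\b", .time_suffix), function(g, s) {
    list(date = ad + 2)
  }, rel_kind)
  scan(paste0("\\bday\\s+before\\s+yesterday\\b"), function(g, s) {
    list(date = ad - 2)
  }, "relative")
  scan("\\bin\\s+([0-9]+|a|an|one|two|three|four|five|six|seven|eight|nine|ten|eleven|twelve)\\s+(hours?|minutes?|days?|weeks?|months?|years?)\\b",
       function(g, s) {
         n <- parse_count(g[1])
         d <- unit_shift(ad, n, g[2])
         list(date = d, sub_day = grepl("^(hour|minute)", tolower(g[2])))
       }, "relative")
  scan("\\b([0-9]+|a|an|one|two|three|four|five|six|seven|eight|nine|ten|eleven|twelve)\\s+(hours?|minutes?|days?|weeks?|months?|years?)\\s+ago\\b",
       function(g, s) {
         n <- parse_count(g[1])
         base <- unit_shift(ad, -n, g[2])
         list(date = base, sub_day = grepl("^(hour|minute)", tolower(g[2])))
       }, "relative")
  scan("\\b(next|last|this)\\s+(week|month|year)\\b", function(g, s) {
    q <- tolower(g[1])
    if (q == "this") return(list(date = ad))
    list(date = unit_shift(ad, if (q == "next") 1 else -1, g[2]))
  }, "relative")
  wd <- paste(names(.weekdays), collapse = "|")
  scan(sprintf("\\b(?:(next|last|this|on)\\s+)?(%s)\\b%s", wd, .time_suffix),
       function(g, s) {
         target <- .weekdays[tolower(g[2])]
         awd <- as.POSIXlt(ad)$wday
         qual <- tolower(g[1])
         if (identical(qual, "last")) {
           back <- (awd - target) %% 7
           if (back == 0) back <- 7
           list(date = ad - back)
         } else if (identical(qual, "next")) {
           fwd <- (target - awd) %% 7
           if (fwd == 0) fwd <- 7
           list(date = ad + fwd)
         } else {  # this / on / bare: nearest forward occurrence, 0-6 ahead
           list(date = ad + (target - awd) %% 7)
         }
       }, rel_kind)
  scan(paste0("\\btomorrow\\b", .time_suffix), function(g, s)
    list(date = ad + 1), rel_kind)
  scan(paste0("\\byesterday\\b", .time_suffix), function(g, s)
    list(date = ad - 1), rel_kind)
  scan(paste0("\\btonight\\b", .time_suffix), function(g, s)
    list(date = ad, sub_day = TRUE), rel_kind)
  scan(paste0("\\btoday\\b", .time_suffix), function(g, s)
    list(date = ad, sub_day = TRUE), rel_kind)

  if (length(rows) == 0) {
    return(data.frame(surface = character(), start = integer(),
                      end = integer(), kind = character(),
                      resolved = as.Date(character()), sub_day = logical(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$start), , drop = FALSE]
}

#' Compute the time-horizon record for one sentence
#'
#' H(s) is the mean over the sentence's temporal references of the signed
#' day-delta D(r) = resolved date - posting date, computed at calendar-date
#' resolution (posting time truncated to its date), so "tomorrow" is always
#' exactly +1 day. \code{raw_delta_days} additionally keeps the fractional
#' delta of the midnight-resolved reference against the full anchor
#' timestamp; it is what exposes same-day midnight-anchoring false positives
#' ("tonight" posted at 16:00 has a raw delta of -16 h).
#'
#' @param exprs Data frame from \code{\link{extract_temporal_expressions}}.
#' @param anchor Posting timestamp.
#' @param sentence_ref Identifier copied onto the record.
#' @return One-row data frame: \code{sentence_ref}, \code{n_refs},
#'   \code{H_days}, \code{abs_H}, \code{log_abs_H} (\code{NA} until
#'   \code{\link{log_abs_horizon}}), \code{t_ref} (0 future, 1 past,
#'   \code{NA} at 0), \code{raw_delta_days}, \code{retained},
#'   \code{drop_reason}.
#' @export
sentence_horizon <- function(exprs, anchor, sentence_ref = NA_character_) {
  if (is.null(exprs) || nrow(exprs) == 0) {
    return(data.frame(sentence_ref = sentence_ref, n_refs = 0L,
                      H_days = NA_real_, abs_H = NA_real_,
                      log_abs_H = NA_real_, t_ref = NA_integer_,
                      raw_delta_days = NA_real_, retained = 0L,
                      drop_reason = "no_expression",
                      stringsAsFactors = FALSE))
  }
  ad <- anchor_date(anchor)
  deltas <- as.numeric(exprs$resolved - ad)
  H <- sum(deltas) / length(deltas)
  anchor_ct <- if (inherits(anchor, "Date"))
    as.POSIXct(paste(anchor, "00:00:00"), tz = "UTC") else anchor
  raw <- mean(as.numeric(difftime(
    as.POSIXct(paste(exprs$resolved, "00:00:00"), tz = "UTC"),
    anchor_ct, units = "days")))
  data.frame(sentence_ref = sentence_ref, n_refs = nrow(exprs),
             H_days = H, abs_H = abs(H), log_abs_H = NA_real_,
             t_ref = if (H > 0) 0L else if (H < 0) 1L else NA_integer_,
             raw_delta_days = raw, retained = 1L, drop_reason = "none",
             stringsAsFactors = FALSE)
}

#' Horizon records for a sentence table
#'
#' Runs the tagger and \code{\link{sentence_horizon}} over every row of a
#' segmented corpus. Sentences whose post lacks a timestamp are an error:
#' horizons cannot be resolved without an anchor.
#'
#' @param sentences Data frame from \code{\link{segment_corpus}} (columns
#'   \code{post_ref}, \code{sent_index}, \code{text}, \code{posted_at}).
#' @param dayfirst Passed to \code{\link{extract_temporal_expressions}}.
#' @return Data frame of horizon records, one per sentence, with
#'   \code{sentence_ref} of the form \code{"<post_ref>:<sent_index>"}.
#' @export
compute_horizons <- function(sentences, dayfirst = TRUE) {
  if (any(is.na(sentences$posted_at)))
    stop("posted_at missing for ",
         sum(is.na(sentences$posted_at)),
         " sentence(s); timestamps are required for horizon resolution")
  recs <- lapply(seq_len(nrow(sentences)), function(i) {
    ex <- extract_temporal_expressions(sentences$text[i],
                                       sentences$posted_at[i],
                                       dayfirst = dayfirst)
    sentence_horizon(ex, sentences$posted_at[i],
                     paste0(sentences$post_ref[i], ":",
                            sentences$sent_index[i]))
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Filter horizon records
#'
#' Drops records with no temporal expressions, and same-day records whose
#' raw (time-of-day) delta is negative — the midnight-anchoring false
#' positives where a future-referring sub-day expression resolves to 00:00
#' of the posting day and so looks like past reference. All other records
#' are retained.
#'
#' @param records Data frame from \code{\link{compute_horizons}}.
#' @param keep_all If \code{TRUE}, return every record with updated
#'   \code{retained}/\code{drop_reason} flags; otherwise (default) only the
#'   retained rows.
#' @return Filtered (or flagged) data frame.
#' @export
filter_horizons <- function(records, keep_all = FALSE) {
  r <- records
  same_day_past <- r$retained == 1L & !is.na(r$H_days) & r$H_days == 0 &
    !is.na(r$raw_delta_days) & r$raw_delta_days < 0
  r$retained[same_day_past] <- 0L
  r$drop_reason[same_day_past] <- "same_day_past"
  n_drop <- sum(r$retained == 0L)
  if (n_drop > 0)
    message(n_drop, " record(s) dropped (",
            sum(r$drop_reason == "no_expression"), " no_expression, ",
            sum(r$drop_reason == "same_day_past"), " same_day_past)")
  if (keep_all) r else r[r$retained == 1L, , drop = FALSE]
}

#' Natural log of the absolute time horizon
#'
#' Sets \code{log_abs_H = ln(abs_H)} on retained records. A retained record
#' with \code{abs_H == 0} cannot be log-transformed; by default this is an
#' error, or with \code{on_zero = "drop"} such records (sub-day references
#' surviving as H = 0) are removed with a message.
#'
#' @param records Data frame of retained horizon records.
#' @param on_zero \code{"error"} (default) or \code{"drop"}.
#' @return Updated data frame.
#' @export
log_abs_horizon <- function(records, on_zero = c("error", "drop")) {
  on_zero <- match.arg(on_zero)
  if (any(records$retained != 1L))
    stop("log_abs_horizon expects retained records; run filter_horizons first")
  zero <- records$abs_H == 0
  if (any(zero)) {
    if (on_zero == "error")
      stop(sum(zero), " retained record(s) with abs_H = 0; ",
           "these should have been filtered")
    message(sum(zero), " record(s) with abs_H = 0 dropped from log scale")
    records <- records[!zero, , drop = FALSE]
  }
  records$log_abs_H <- log(records$abs_H)
  records
}
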