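# Closed-vocabulary FTR-type classification.
#
# Future-referring sentences are assigned to tense/modal semantic categories
# by keyword presence. Modal categories dominate tense categories; negated
# and mixed-modal (high- plus low-certainty) sentences are excluded because
# keyword methods cannot recover the intended modal polarity there.

.type_flags <- c("future_tense", "present_tense", "verbal_low_certainty",
                 "other_low_certainty", "other_high_certainty",
                 "verbal_high_certainty", "deontic", "bouletic", "irrealis")

#' The default modal/tense lexicon
#'
#' Keyword lists per category, each keyword a (possibly multi-word) token
#' sequence matched case-insensitively on token boundaries after contraction
#' expansion. The periphrastic future "be going to" is matched as
#' am/is/are/was/were + "going to"; "have to"/"need to" cover their
#' inflections. \code{verbal_high_certainty} ships empty: it is a recognised
#' category slot whose trigger vocabulary is not defined by default, so it
#' never fires unless configured. The lexicon is versioned and fully
#' overridable (see \code{\link{read_lexicon}}).
#'
#' @return A list of class \code{"ftr_lexicon"}: one character vector per
#'   category plus \code{negation}, a \code{word_class} map and a
#'   \code{version} string.
#' @export
default_lexicon <- function() {
  lex <- list(
    future_tense = c("will", "shall",
                     "am going to", "is going to", "are going to",
                     "was going to", "were going to", "going to"),
    verbal_low_certainty = c("could", "may", "might", "should"),
    other_low_certainty = c("possibly", "probably", "potentially",
                            "possible", "probable", "possibility",
                            "probability", "perhaps", "maybe", "likely",
                            "i think", "i guess", "i suppose", "i reckon"),
    other_high_certainty = c("definitely", "certainly", "absolutely",
                             "certain", "surely", "for sure",
                             "undoubtedly"),
    verbal_high_certainty = character(0),
    deontic = c("must", "have to", "has to", "had to", "having to",
                "need to", "needs to", "needed to", "needing to"),
    bouletic = c("hope", "hopes", "hoped", "hoping",
                 "want", "wants", "wanted", "wanting",
                 "wish", "wishes", "wished", "wishing",
                 "would like to"),
    irrealis = c("if", "would"),
    negation = c("not", "never")
  )
  lex$word_class <- c(future_tense = "verbal",
                      verbal_low_certainty = "verbal",
                      other_low_certainty = "other",
                      other_high_certainty = "other",
                      verbal_high_certainty = "verbal",
                      deontic = "verbal", bouletic = "verbal",
                      irrealis = "other")
  lex$version <- "1.0"
  validate_lexicon(lex)
}

validate_lexicon <- function(lex) {
  cats <- setdiff(names(lex), c("word_class", "version", "negation"))
  all_keys <- unlist(lex[cats], use.names = FALSE)
  # "would" is deliberately shared between irrealis and the "would like to"
  # bouletic pattern head; uniqueness is enforced on full keys, not tokens.
  if (anyDuplicated(all_keys))
    stop("lexicon keyword(s) in more than one category: ",
         paste(unique(all_keys[duplicated(all_keys)]), collapse = ", "))
  structure(lex, class = c("ftr_lexicon", "list"))
}

#' Read a lexicon override from a JSON config
#'
#' Categories present in the file replace the defaults; categories absent
#' keep their default lists.
#'
#' @param path JSON file mapping category names to keyword arrays.
#' @return An \code{"ftr_lexicon"}.
#' @export
read_lexicon <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  lex <- default_lexicon()
  for (nm in names(cfg)) {
    if (nm %in% c("word_class", "version")) { lex[[nm]] <- cfg[[nm]]; next }
    if (!nm %in% names(lex)) stop("unknown lexicon category: ", nm)
    lex[[nm]] <- as.character(cfg[[nm]])
  }
  validate_lexicon(lex)
}

# Does any keyword (token sequence) of `keys` occur in `tokens`?
match_any_key <- function(tokens, keys) {
  if (length(keys) == 0 || length(tokens) == 0) return(FALSE)
  for (k in keys) {
    kt <- strsplit(k, " ", fixed = TRUE)[[1]]
    L <- length(kt)
    if (L == 1) {
      if (kt %in% tokens) return(TRUE)
    } else if (length(tokens) >= L) {
      for (s in seq_len(length(tokens) - L + 1L)) {
        if (all(tokens[s:(s + L - 1L)] == kt)) return(TRUE)
      }
    }
  }
  FALSE
}

#' Detect negation
#'
#' 1 iff any negation keyword is present as a token after contraction
#' expansion ("won't" expands to "will not" and so triggers). Presence
#' anywhere in the sentence counts: scope is not resolved, matching the
#' wholesale exclusion policy.
#'
#' @param text Sentence text (character vector; vectorised).
#' @param lexicon An \code{"ftr_lexicon"}; defaults to
#'   \code{\link{default_lexicon}}.
#' @return Integer 0/1 vector.
#' @export
detect_negation <- function(text, lexicon = default_lexicon()) {
  toks <- tokenize(text)
  vapply(toks, function(t) as.integer(match_any_key(t, lexicon$negation)),
         integer(1))
}

#' Detect mixed-modal expressions
#'
#' 1 iff at least one high-certainty keyword (verbal or other) and at least
#' one low-certainty keyword (verbal or other) are both present; such
#' sentences are excluded because the intended polarity is unrecoverable by
#' keyword matching.
#'
#' @inheritParams detect_negation
#' @return Integer 0/1 vector.
#' @export
detect_mixed_modal <- function(text, lexicon = default_lexicon()) {
  toks <- tokenize(text)
  lo <- c(lexicon$verbal_low_certainty, lexicon$other_low_certainty)
  hi <- c(lexicon$verbal_high_certainty, lexicon$other_high_certainty)
  vapply(toks, function(t) {
    as.integer(match_any_key(t, lo) && match_any_key(t, hi))
  }, integer(1))
}

#' Classify the FTR type of future-referring sentences
#'
#' Applies the exclusion rules first (negation, then mixed-modal); otherwise
#' sets every matched modal category flag (the result is a flag set, and the
#' low-certainty verbal/other pair may legitimately co-occur under modal
#' concord). Modal flags dominate tense flags: any modal match zeroes both
#' tense categories. With no modal match, a future-tense keyword sets
#' \code{future_tense}; otherwise the sentence falls into the residual
#' \code{present_tense} category. The caller is responsible for only passing
#' sentences already judged future-referring.
#'
#' @param text Character vector of sentence texts.
#' @param lexicon An \code{"ftr_lexicon"}.
#' @return Data frame with one row per sentence: the nine 0/1 category
#'   flags, \code{excluded} and \code{exclusion_reason} (\code{"none"},
#'   \code{"negation"} or \code{"mixed_modal"}).
#' @export
classify_ftr_type <- function(text, lexicon = default_lexicon()) {
  toks <- tokenize(text)
  n <- length(toks)
  out <- as.data.frame(matrix(0L, nrow = n, ncol = length(.type_flags),
                              dimnames = list(NULL, .type_flags)))
  out$excluded <- 0L
  out$exclusion_reason <- rep("none", n)
  modal_cats <- c("verbal_low_certainty", "other_low_certainty",
                  "other_high_certainty", "verbal_high_certainty",
                  "deontic", "bouletic", "irrealis")
  for (i in seq_len(n)) {
    t <- toks[[i]]
    if (match_any_key(t, lexicon$negation)) {
      out$excluded[i] <- 1L
      out$exclusion_reason[i] <- "negation"
      next
    }
    lo <- c(lexicon$verbal_low_certainty, lexicon$other_low_certainty)
    hi <- c(lexicon$verbal_high_certainty, lexicon$other_high_certainty)
    if (match_any_key(t, lo) && match_any_key(t, hi)) {
      out$excluded[i] <- 1L
      out$exclusion_reason[i] <- "mixed_modal"
      next
    }
    any_modal <- FALSE
    for (cat in modal_cats) {
      if (match_any_key(t, lexicon[[cat]])) {
        out[[cat]][i] <- 1L
        any_modal <- TRUE
      }
    }
    if (!any_modal) {
      if (match_any_key(t, lexicon$future_tense)) {
        out$future_tense[i] <- 1L
      } else {
        out$present_tense[i] <- 1L
      }
    }
  }
  out
}

#' Proportional breakdown of FTR types
#'
#' Per-category means of the dichotomous flags, renormalised to sum to 1
#' (excluded rows must be removed first; rows where \code{excluded == 1}
#' are an error).
#'
#' @param labelsets Data frame from \code{\link{classify_ftr_type}} (or any
#'   data frame containing the nine flag columns).
#' @param group Optional vector of group labels (e.g. condition); if given,
#'   a matrix with one row per group is returned.
#' @return Named numeric vector of proportions summing to 1 (or a matrix by
#'   group, each row summing to 1).
#' @export
proportions_by_type <- function(labelsets, group = NULL) {
  if (nrow(labelsets) == 0) stop("empty label set")
  if (!is.null(labelsets$excluded) && any(labelsets$excluded == 1))
    stop("excluded records must be removed before computing proportions")
  flags <- labelsets[, .type_flags, drop = FALSE]
  one <- function(df) {
    m <- colMeans(as.matrix(df))
    s <- sum(m)
    if (s == 0) stop("all flags zero; proportions undefined")
    m / s
  }
  if (is.null(group)) return(one(flags))
  gs <- split(flags, group)
  if (any(vapply(gs, nrow, integer(1)) == 0)) stop("empty group")
  do.call(rbind, lapply(gs, one))
}
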