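# Tokenisation shared by the time-reference model and the FTR-type lexicon.
# Keyword matching must see the underlying modal/negator, so contractions are
# expanded before splitting ("won't" -> "will not", "I'll" -> "I will").

.contractions <- list(
  c("won't",   "will not"),
  c("shan't",  "shall not"),
  c("can't",   "can not"),
  c("cannot",  "can not"),
  c("ain't",   "is not"),
  c("n't",     " not"),      # generic: don't -> do not, isn't -> is not
  c("'ll",     " will"),
  c("'m",      " am"),
  c("'re",     " are"),
  c("'ve",     " have"),
  c("'d",      " would"),
  c("'s",      " is"),       # ambiguous with possessives; harmless for matching
  c("gonna",   "going to"),
  c("wanna",   "want to"),
  c("gotta",   "have to")
)

#' Expand English contractions
#'
#' @param text Character vector.
#' @return Character vector with contractions expanded (case-insensitive;
#'   output is lower-cased).
#' @export
expand_contractions <- function(text) {
  x <- tolower(text)
  # unicode apostrophe variants
  x <- gsub("’", "'", x)
  for (pair in .contractions) {
    pat <- pair[1]
    if (pat %in% c("won't", "shan't", "can't", "cannot", "ain't",
                   "gonna", "wanna", "gotta")) {
      x <- gsub(paste0("\\b", pat, "\\b"), pair[2], x, perl = TRUE)
    } else {
      x <- gsub(pat, pair[2], x, fixed = TRUE)
    }
  }
  x
}

#' Tokenize text
#'
#' Lower-cases, expands contractions, and splits on whitespace and
#' punctuation (internal hyphens/apostrophes retained).
#'
#' @param text Character vector (each element tokenized separately).
#' @return List of character vectors of tokens.
#' @export
tokenize <- function(text) {
  x <- expand_contractions(text)
  x <- gsub("[^a-z0-9'\\-]+", " ", x)
  x <- gsub("(^|\\s)['-]+|['-]+(\\s|$)", " ", x)
  lapply(strsplit(trimws(x), "\\s+"), function(t) t[nzchar(t)])
}
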