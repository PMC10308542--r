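#' Confusion-matrix classification metrics
#'
#' Accuracy, precision, recall and F1 from true/false positive/negative
#' counts: a = (tp+tn)/(tp+fp+fn+tn), p = tp/(tp+fp), r = tp/(tp+fn),
#' F1 = 2rp/(r+p). Ratios with a zero denominator are reported as \code{NA}
#' (absent), never as 0.
#'
#' @param tp,fp,fn,tn Non-negative integer counts.
#' @return A list of class \code{"classifier_metrics"} with the four counts
#'   and the four metrics.
#' @export
classifier_metrics <- function(tp, fp, fn, tn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  total <- tp + fp + fn + tn
  acc <- if (total > 0) (tp + tn) / total else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0)
    2 * rec * prec / (rec + prec) else NA_real_
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 accuracy = acc, precision = prec, recall = rec, f1 = f1),
            class = "classifier_metrics")
}

#' @export
print.classifier_metrics <- function(x, ...) {
  cat(sprintf("tp=%d fp=%d fn=%d tn=%d\n", x$tp, x$fp, x$fn, x$tn))
  cat(sprintf("accuracy=%.3f precision=%s recall=%s f1=%s\n",
              x$accuracy, fmt_na(x$precision), fmt_na(x$recall),
              fmt_na(x$f1)))
  invisible(x)
}

fmt_na <- function(v) if (is.na(v)) "absent" else sprintf("%.3f", v)

# ---- feature extraction -----------------------------------------------------

ngram_features <- function(tokens) {
  # unigrams + bigrams
  if (length(tokens) == 0) return(character(0))
  uni <- tokens
  bi <- if (length(tokens) > 1)
    paste(tokens[-length(tokens)], tokens[-1], sep = "_") else character(0)
  c(uni, bi)
}

build_dtm <- function(texts, vocab = NULL) {
  feats <- lapply(tokenize(texts), ngram_features)
  if (is.null(vocab)) vocab <- sort(unique(unlist(feats)))
  idx <- lapply(feats, function(f) {
    m <- match(f, vocab)
    m[!is.na(m)]
  })
  i <- rep(seq_along(idx), lengths(idx))
  j <- unlist(idx)
  x <- rep(1, length(j))
  m <- Matrix::sparseMatrix(i = i, j = j, x = x,
                            dims = c(length(texts), length(vocab)))
  # presence counts (duplicated (i,j) summed by sparseMatrix)
  list(dtm = m, vocab = vocab)
}

effective_labels <- function(examples) {
  lab <- as.character(examples$target_label)
  if (!is.null(examples$decision)) {
    dec <- as.character(examples$decision)
    keep <- dec != "ignore"
    lab <- ifelse(dec == "reject", "OTHER", lab)
    return(list(text = examples$text[keep], label = lab[keep]))
  }
  list(text = examples$text, label = lab)
}

# ---- training ---------------------------------------------------------------

#' Train the sentence-level time-reference classifier
#'
#' Fits a bag-of-n-grams (unigram + bigram) linear model with a three-way
#' softmax over \{FTR, PTR, OTHER\} via ridge-penalised multinomial
#' regression. The fit itself is convex and deterministic; the seed drives
#' only the train/held-out split. Annotation decisions are honoured:
#' \code{ignore} rows are excluded, \code{reject} rows become OTHER.
#'
#' @param examples Data frame with columns \code{text},
#'   \code{target_label} (\code{"FTR"}, \code{"PTR"} or \code{"OTHER"}) and
#'   optionally \code{decision} (\code{"accept"}, \code{"reject"},
#'   \code{"ignore"}).
#' @param split Training fraction (default 0.8; the remainder is the
#'   held-out evaluation set).
#' @param seed Integer seed for the split.
#' @param lambda Ridge penalty (fixed, not cross-validated, so training is a
#'   single deterministic convex fit).
#' @param class_weights If \code{TRUE}, reweight classes inversely to their
#'   frequency. Default \code{FALSE} (no reweighting).
#' @return An object of class \code{"ftr_time_model"} with elements
#'   \code{vocab}, \code{weights} (feature-by-class matrix),
#'   \code{intercepts}, \code{classes}, and \code{holdout_metrics} (per-label
#'   \code{\link{classifier_metrics}} on the held-out fraction).
#' @export
train_time_reference <- function(examples, split = 0.8, seed = 1,
                                 lambda = 0.01, class_weights = FALSE) {
  eff <- effective_labels(examples)
  texts <- eff$text
  labels <- factor(eff$label, levels = c("FTR", "PTR", "OTHER"))
  if (any(is.na(labels))) stop("labels must be FTR, PTR or OTHER")
  if (length(unique(labels[!is.na(labels)])) < 2)
    stop("training data must contain at least 2 classes")
  n <- length(texts)
  set.seed(as.integer(seed))
  train_idx <- sort(sample.int(n, size = max(2L, floor(split * n))))
  test_idx <- setdiff(seq_len(n), train_idx)
  if (length(unique(labels[train_idx])) < 2)
    stop("training split contains a single class; change seed or split")

  bd <- build_dtm(texts[train_idx])
  y <- droplevels(labels[train_idx])
  w <- rep(1, length(y))
  if (class_weights) {
    tab <- table(y)
    w <- as.numeric(length(y) / (length(tab) * tab[y]))
  }
  fit <- glmnet::glmnet(bd$dtm, y, family = "multinomial", alpha = 0,
                        lambda = lambda, standardize = FALSE, weights = w)
  cf <- stats::coef(fit, s = lambda)
  classes <- names(cf)
  W <- do.call(cbind, lapply(cf, function(m) as.numeric(m[-1, 1])))
  b <- vapply(cf, function(m) m[1, 1], numeric(1))
  colnames(W) <- classes
  rownames(W) <- bd$vocab

  model <- structure(list(
    vocab = bd$vocab, weights = W, intercepts = b, classes = classes,
    lambda = lambda, seed = as.integer(seed), split = split,
    n_train = length(train_idx), n_test = length(test_idx)
  ), class = "ftr_time_model")

  model$holdout_metrics <- if (length(test_idx) > 0) {
    evaluate_time_reference(model,
      data.frame(text = texts[test_idx],
                 target_label = as.character(labels[test_idx]),
                 stringsAsFactors = FALSE))
  } else NULL
  model
}

softmax_scores <- function(model, texts) {
  bd <- build_dtm(texts, vocab = model$vocab)
  eta <- as.matrix(bd$dtm %*% model$weights)
  eta <- sweep(eta, 2, model$intercepts, "+")
  eta <- eta - apply(eta, 1, max)
  ex <- exp(eta)
  p <- ex / rowSums(ex)
  colnames(p) <- model$classes
  p
}

#' Predict time reference for sentences
#'
#' Returns per-sentence softmax probabilities for FTR and PTR and the
#' corresponding binary flags, binarised at 0.5 with \code{>=} (so a
#' probability of exactly 0.5 is a positive call). Empty sentences are
#' assigned the residual class by convention (both probabilities 0) and a
#' message is emitted.
#'
#' @param object An \code{"ftr_time_model"}.
#' @param newdata Character vector of sentence texts, or a data frame with a
#'   \code{text} column.
#' @param ... Unused.
#' @return Data frame with columns \code{text}, \code{p_ftr}, \code{p_ptr},
#'   \code{is_ftr}, \code{is_ptr}, \code{label} (argmax class).
#' @export
predict.ftr_time_model <- function(object, newdata, ...) {
  texts <- if (is.data.frame(newdata)) newdata$text else as.character(newdata)
  empty <- !nzchar(trimws(texts))
  if (any(empty))
    message(sum(empty), " empty sentence(s) assigned OTHER with p = 0")
  p <- matrix(0, nrow = length(texts), ncol = length(object$classes),
              dimnames = list(NULL, object$classes))
  if (any(!empty)) p[!empty, ] <- softmax_scores(object, texts[!empty])
  p_ftr <- if ("FTR" %in% colnames(p)) p[, "FTR"] else rep(0, nrow(p))
  p_ptr <- if ("PTR" %in% colnames(p)) p[, "PTR"] else rep(0, nrow(p))
  label <- object$classes[max.col(p, ties.method = "first")]
  label[empty] <- "OTHER"
  p_ftr[empty] <- 0; p_ptr[empty] <- 0
  out <- data.frame(text = texts,
                    p_ftr = unname(p_ftr), p_ptr = unname(p_ptr),
                    is_ftr = binarize_half(p_ftr),
                    is_ptr = binarize_half(p_ptr),
                    label = label, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Binarise a probability at 0.5
#'
#' The split is inclusive: \code{f(p) = 1} iff \code{p >= 0.5}.
#'
#' @param p Numeric vector of probabilities.
#' @return Integer vector of 0/1 flags.
#' @export
binarize_half <- function(p) as.integer(p >= 0.5)

#' Evaluate the time-reference model on annotated examples
#'
#' Computes per-label confusion counts and metrics. For FTR and PTR the
#' positive prediction is the binarised probability flag; for OTHER it is
#' the binarised residual probability.
#'
#' @param model An \code{"ftr_time_model"}.
#' @param test Data frame with \code{text} and \code{target_label} (and
#'   optionally \code{decision}) columns.
#' @return Named list of \code{\link{classifier_metrics}}, one per label
#'   present in the model.
#' @export
evaluate_time_reference <- function(model, test) {
  eff <- effective_labels(test)
  if (length(eff$text) == 0) stop("test set is empty")
  pred <- predict(model, eff$text)
  p_other <- 1 - pred$p_ftr - pred$p_ptr
  flags <- list(FTR = pred$is_ftr, PTR = pred$is_ptr,
                OTHER = binarize_half(p_other))
  out <- lapply(model$classes, function(cl) {
    truth <- as.integer(eff$label == cl)
    f <- flags[[cl]]
    classifier_metrics(tp = sum(f == 1 & truth == 1),
                       fp = sum(f == 1 & truth == 0),
                       fn = sum(f == 0 & truth == 1),
                       tn = sum(f == 0 & truth == 0))
  })
  names(out) <- model$classes
  out
}

#' @export
print.ftr_time_model <- function(x, ...) {
  cat("Time-reference classifier (bag of 1-2 grams, ridge multinomial)\n")
  cat(sprintf("  vocabulary: %d features; classes: %s\n",
              length(x$vocab), paste(x$classes, collapse = ", ")))
  cat(sprintf("  trained on %d examples (seed %d), held out %d\n",
              x$n_train, x$seed, x$n_test))
  if (!is.null(x$holdout_metrics)) {
    for (cl in names(x$holdout_metrics)) {
      m <- x$holdout_metrics[[cl]]
      cat(sprintf("  %-5s acc=%.3f prec=%s rec=%s f1=%s\n", cl,
                  m$accuracy, fmt_na(m$precision), fmt_na(m$recall),
                  fmt_na(m$f1)))
    }
  }
  invisible(x)
}

#' Serialize / restore a time-reference model as JSON
#'
#' The model is a vocabulary plus a dense weight matrix, so a single JSON
#' file round-trips it exactly.
#'
#' @param model An \code{"ftr_time_model"}.
#' @param path File path.
#' @return \code{read_time_model} returns the restored model.
#' @export
write_time_model <- function(model, path) {
  obj <- list(vocab = model$vocab,
              weights = unname(as.list(as.data.frame(model$weights))),
              intercepts = as.numeric(model$intercepts),
              classes = model$classes, lambda = model$lambda,
              seed = model$seed, split = model$split,
              n_train = model$n_train, n_test = model$n_test)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_time_model
#' @export
read_time_model <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyMatrix = FALSE)
  W <- do.call(cbind, lapply(obj$weights, unlist))
  colnames(W) <- obj$classes
  rownames(W) <- obj$vocab
  b <- as.numeric(obj$intercepts)
  names(b) <- obj$classes
  structure(list(vocab = obj$vocab, weights = W, intercepts = b,
                 classes = obj$classes, lambda = obj$lambda,
                 seed = obj$seed, split = obj$split,
                 n_train = obj$n_train, n_test = obj$n_test),
            class = "ftr_time_model")
}
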