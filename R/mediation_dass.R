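# DASS-21 scoring, time-slider aggregation, and the two-equation mediation
# model:
#   M_i = lambda1 + alpha1*anx_i + alpha2*dep_i + e1_i
#   Y_i = lambda2 + tau1*anx_i + tau2*dep_i + beta*M_i + e2_i
# with Y = log(k) discounting, M = mean subjective temporal distance.
# Indirect effect of predictor j = alpha_j * beta; total = indirect + direct.

#' Default DASS-21 item-to-dimension map
#'
#' The standard assignment of the 21 items to the three 7-item subscales.
#'
#' @return Named list of integer item indices for \code{depression},
#'   \code{anxiety}, \code{stress}.
#' @export
dass_item_map <- function() {
  list(depression = c(3L, 5L, 10L, 13L, 16L, 17L, 21L),
       anxiety = c(2L, 4L, 7L, 9L, 15L, 19L, 20L),
       stress = c(1L, 6L, 8L, 11L, 12L, 14L, 18L))
}

#' Score the DASS-21
#'
#' Each dimension's score is twice the sum of its 7 item responses
#' (each item 0-3), so scores range 0-42.
#'
#' @param items Numeric vector of 21 item responses in \code{\{0,1,2,3\}},
#'   in questionnaire order; or a matrix/data frame with 21 columns (one
#'   row per participant).
#' @param item_map Item-to-dimension assignment
#'   (default \code{\link{dass_item_map}}).
#' @return Data frame with columns \code{depression}, \code{anxiety},
#'   \code{stress} (integers in [0, 42]).
#' @export
score_dass <- function(items, item_map = dass_item_map()) {
  if (is.vector(items)) items <- matrix(items, nrow = 1)
  items <- as.matrix(items)
  if (ncol(items) != 21)
    stop("expected 21 items, got ", ncol(items))
  bad <- which(is.na(items) | items < 0 | items > 3 | items != round(items),
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("missing or out-of-range item(s): ",
         paste(sprintf("row %d item %d", bad[, 1], bad[, 2]), collapse = "; "))
  }
  stopifnot(all(lengths(item_map) == 7))
  out <- data.frame(
    depression = 2L * as.integer(rowSums(items[, item_map$depression, drop = FALSE])),
    anxiety = 2L * as.integer(rowSums(items[, item_map$anxiety, drop = FALSE])),
    stress = 2L * as.integer(rowSums(items[, item_map$stress, drop = FALSE])))
  stopifnot(all(as.matrix(out) >= 0), all(as.matrix(out) <= 42))
  out
}

#' Mean subjective temporal distance
#'
#' Aggregates a participant's time-slider ratings (0 = "close to now",
#' 100 = "far from now", one per delay) to their arithmetic mean, the
#' mediating variable of the mediation model. Order-invariant.
#'
#' @param ratings Numeric vector of ratings in [0, 100].
#' @return Scalar mean rating.
#' @export
mean_subjective_distance <- function(ratings) {
  ratings <- as.numeric(ratings)
  if (length(ratings) == 0) stop("at least one rating required")
  if (any(is.na(ratings)) || any(ratings < 0) || any(ratings > 100))
    stop("ratings must be in [0, 100]")
  mean(ratings)
}

# Fast OLS on a fixed design; returns coefficients, fitted and residuals.
ols_fit <- function(X, y) {
  fit <- stats::lm.fit(X, y)
  if (any(is.na(fit$coefficients)))
    stop("collinear or constant predictors: design matrix is rank deficient")
  fit
}

boot_r2 <- function(fitted, resid) {
  vf <- stats::var(fitted)
  vf / (vf + stats::var(resid))
}

.effect_names <- c("lambda1", "alpha1", "alpha2",
                   "lambda2", "tau1", "tau2", "beta",
                   "indirect_anx", "indirect_dep",
                   "direct_anx", "direct_dep",
                   "total_anx", "total_dep",
                   "r2_m", "r2_y")

mediation_draw <- function(anx, dep, M, Y) {
  n <- length(Y)
  X1 <- cbind(1, anx, dep)
  f1 <- ols_fit(X1, M)
  X2 <- cbind(1, anx, dep, M)
  f2 <- ols_fit(X2, Y)
  c1 <- unname(f1$coefficients)
  c2 <- unname(f2$coefficients)
  out <- c(c1[1], c1[2], c1[3],
           c2[1], c2[2], c2[3], c2[4],
           c1[2] * c2[4], c1[3] * c2[4],
           c2[2], c2[3],
           c1[2] * c2[4] + c2[2], c1[3] * c2[4] + c2[3],
           boot_r2(f1$fitted.values, f1$residuals),
           boot_r2(f2$fitted.values, f2$residuals))
  names(out) <- .effect_names
  out
}

#' Fit the two-equation mediation model
#'
#' Point estimates are ordinary least squares on the two equations;
#' uncertainty comes from nonparametric case-resampling: each draw refits
#' both equations on the same resampled participants, so the draw-wise
#' identity \code{total = indirect + direct} holds exactly within every
#' draw. One-tailed posterior-style probabilities (\code{pp}) are the
#' fraction of draws whose sign matches the predicted direction for that
#' effect. Central intervals are reported at 90\% and 95\%. R-squared per
#' equation is draw-wise explained variance over explained-plus-residual
#' (empirical residual variance).
#'
#' @param data Data frame with columns \code{anxiety}, \code{depression},
#'   \code{mean_subj_dist} (mediator M) and \code{log_k} (outcome Y).
#' @param n_draws Number of resampling draws (default 4000).
#' @param seed Integer seed for the resampling.
#' @param directions Named numeric vector of predicted signs (+1/-1) for
#'   the directional effects; defaults to +1 for every anxiety/depression
#'   effect. Names as in the summary table (e.g. \code{"indirect_anx"}).
#' @param standardize If \code{TRUE}, z-score predictors, M and Y before
#'   fitting (standardized effects). Default \code{FALSE}: variables enter
#'   raw.
#' @return Object of class \code{"ftr_mediation"}: list with \code{point}
#'   (named vector), \code{draws} (n_draws x effect matrix),
#'   \code{summary} (data frame with \code{estimate}, \code{lo95},
#'   \code{lo90}, \code{hi90}, \code{hi95}, \code{pp}), \code{n},
#'   \code{n_draws}, \code{seed}.
#' @export
fit_mediation <- function(data, n_draws = 4000, seed = 1,
                          directions = NULL, standardize = FALSE) {
  need <- c("anxiety", "depression", "mean_subj_dist", "log_k")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  cc <- stats::complete.cases(data[, need])
  data <- data[cc, , drop = FALSE]
  n <- nrow(data)
  if (n < 10) stop("need at least 10 complete cases, got ", n)
  z <- function(x) (x - mean(x)) / stats::sd(x)
  anx <- data$anxiety; dep <- data$depression
  M <- data$mean_subj_dist; Y <- data$log_k
  if (standardize) { anx <- z(anx); dep <- z(dep); M <- z(M); Y <- z(Y) }
  if (stats::sd(anx) == 0 || stats::sd(dep) == 0)
    stop("constant predictor")
  if (abs(stats::cor(anx, dep)) > 1 - 1e-12)
    stop("anxiety and depression are collinear to machine precision")

  point <- mediation_draw(anx, dep, M, Y)
  set.seed(as.integer(seed))
  draws <- matrix(NA_real_, nrow = n_draws, ncol = length(.effect_names),
                  dimnames = list(NULL, .effect_names))
  for (b in seq_len(n_draws)) {
    idx <- sample.int(n, n, replace = TRUE)
    draws[b, ] <- tryCatch(
      mediation_draw(anx[idx], dep[idx], M[idx], Y[idx]),
      error = function(e) rep(NA_real_, length(.effect_names)))
  }
  ok <- stats::complete.cases(draws)
  if (!all(ok)) {
    message(sum(!ok), " degenerate resample(s) discarded")
    draws <- draws[ok, , drop = FALSE]
  }

  dir_default <- stats::setNames(rep(1, length(.effect_names)), .effect_names)
  if (!is.null(directions)) dir_default[names(directions)] <- directions
  smry <- summarize_draws(draws, point, dir_default)

  structure(list(point = point, draws = draws, summary = smry,
                 n = n, n_draws = n_draws, seed = as.integer(seed),
                 standardized = standardize),
            class = "ftr_mediation")
}

summarize_draws <- function(draws, point, directions) {
  qs <- apply(draws, 2, stats::quantile,
              probs = c(0.025, 0.05, 0.95, 0.975), names = FALSE)
  pp <- vapply(colnames(draws), function(nm) {
    mean(sign(draws[, nm]) == directions[nm] | draws[, nm] == 0)
  }, numeric(1))
  data.frame(effect = colnames(draws),
             estimate = unname(point[colnames(draws)]),
             mean_draw = colMeans(draws),
             lo95 = qs[1, ], lo90 = qs[2, ], hi90 = qs[3, ], hi95 = qs[4, ],
             pp = unname(pp), row.names = NULL, stringsAsFactors = FALSE)
}

#' Decompose path draws into indirect, direct and total effects
#'
#' Given per-draw path coefficients, forms the per-draw products and sums
#' (the same draw indices are used throughout, so total = indirect + direct
#' identically per draw) and summarises them by means and central
#' intervals.
#'
#' @param alpha,beta,tau Numeric vectors of equal length: per-draw X->M,
#'   M->Y and direct X->Y coefficients.
#' @param probs Interval coverage levels (default 0.90 and 0.95).
#' @return List with \code{draws} (data frame of \code{indirect},
#'   \code{direct}, \code{total}) and \code{summary} (mean and quantile
#'   bounds per effect).
#' @export
effect_decomposition <- function(alpha, beta, tau, probs = c(0.90, 0.95)) {
  stopifnot(length(alpha) == length(beta), length(beta) == length(tau))
  if (length(alpha) == 0) stop("no draws")
  d <- data.frame(indirect = alpha * beta, direct = tau,
                  total = alpha * beta + tau)
  qlev <- sort(unique(c((1 - probs) / 2, 1 - (1 - probs) / 2)))
  smry <- t(vapply(d, function(x) {
    c(mean = mean(x), stats::quantile(x, probs = qlev, names = TRUE))
  }, numeric(1 + length(qlev))))
  list(draws = d, summary = as.data.frame(smry))
}

#' @export
print.ftr_mediation <- function(x, ...) {
  cat(sprintf("Mediation model (bootstrap, %d draws, n = %d)\n",
              nrow(x$draws), x$n))
  show <- c("indirect_anx", "direct_anx", "total_anx",
            "indirect_dep", "direct_dep", "total_dep")
  s <- x$summary[x$summary$effect %in% show, ]
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-13s %6.3f  90%% [%6.3f, %6.3f]  95%% [%6.3f, %6.3f]  pp=%.3f\n",
                s$effect[i], s$estimate[i], s$lo90[i], s$hi90[i],
                s$lo95[i], s$hi95[i], s$pp[i]))
  }
  r2 <- x$summary[x$summary$effect %in% c("r2_m", "r2_y"), ]
  cat(sprintf("  R2(M) = %.3f [%.3f, %.3f]; R2(Y) = %.3f [%.3f, %.3f]\n",
              r2$estimate[1], r2$lo95[1], r2$hi95[1],
              r2$estimate[2], r2$lo95[2], r2$hi95[2]))
  invisible(x)
}

#' @export
summary.ftr_mediation <- function(object, ...) object$summary

#' @export
coef.ftr_mediation <- function(object, ...) {
  object$point[c("lambda1", "alpha1", "alpha2",
                 "lambda2", "tau1", "tau2", "beta")]
}
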