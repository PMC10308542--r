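# Intertemporal-choice battery and Kirby-style hyperbolic discounting.
#
# Each item offers a smaller-sooner reward (SSR, immediate) against a
# larger-later reward fixed at GBP 100 after a delay. Under hyperbolic
# discounting the delayed reward's subjective value is V = A / (1 + kD);
# a participant's k is estimated by scoring every indifference-point
# candidate k against their empirical choices.

#' Delay labels and their day equivalents
#'
#' The battery's 11 delays. The label-to-days mapping follows the standard
#' convention for this task family (later today = 0 through ten years =
#' 3650 days) and is configurable wherever a battery is built.
#'
#' @return Named numeric vector (days), names are the delay labels.
#' @export
default_delay_map <- function() {
  c("later today" = 0, "tomorrow" = 1, "one week" = 7, "one month" = 30,
    "two months" = 61, "three months" = 91, "six months" = 182,
    "one year" = 365, "two years" = 730, "five years" = 1825,
    "ten years" = 3650)
}

#' Build the intertemporal-choice battery
#'
#' Fully crosses the 10 smaller-sooner amounts (GBP 50-95 by 5) with the 11
#' delays, giving exactly 110 items; the larger-later reward is fixed at
#' GBP 100. Presentation order is a separate, seeded permutation: the
#' returned battery is in canonical (amount x delay) order unless
#' \code{shuffle_seed} is given.
#'
#' @param llr Larger-later reward (default 100).
#' @param ssr_amounts Smaller-sooner amounts (default \code{seq(50, 95, 5)}).
#' @param delay_map Named vector of delay label -> days
#'   (default \code{\link{default_delay_map}}).
#' @param shuffle_seed Optional integer; if given, rows are returned in a
#'   seeded random presentation order.
#' @return Data frame with columns \code{item_id}, \code{ssr}, \code{llr},
#'   \code{delay_label}, \code{delay_days}.
#' @export
generate_battery <- function(llr = 100, ssr_amounts = seq(50, 95, by = 5),
                             delay_map = default_delay_map(),
                             shuffle_seed = NULL) {
  stopifnot(all(ssr_amounts < llr))
  grid <- expand.grid(ssr = ssr_amounts, delay_label = names(delay_map),
                      stringsAsFactors = FALSE)
  bat <- data.frame(item_id = seq_len(nrow(grid)), ssr = grid$ssr,
                    llr = llr, delay_label = grid$delay_label,
                    delay_days = unname(delay_map[grid$delay_label]),
                    stringsAsFactors = FALSE)
  if (!is.null(shuffle_seed)) {
    set.seed(as.integer(shuffle_seed))
    bat <- bat[sample.int(nrow(bat)), , drop = FALSE]
    rownames(bat) <- NULL
  }
  bat
}

#' Hyperbolic subjective value
#'
#' V = A / (1 + kD): the present subjective value of reward A delayed by D
#' days under discount rate k (per day). Larger k means steeper
#' devaluation.
#'
#' @param A Reward amount (non-negative).
#' @param k Discount rate per day (non-negative).
#' @param D Delay in days (non-negative).
#' @return Subjective value, same units as \code{A}.
#' @export
hyperbolic_value <- function(A, k, D) {
  if (any(A < 0) || any(k < 0) || any(D < 0))
    stop("A, k and D must be non-negative")
  A / (1 + k * D)
}

# Single shared comparator: predicted choice is larger-later (1) iff its
# discounted value strictly exceeds the immediate amount; exact equality
# predicts the immediate choice.
predict_choice <- function(k, ssr, llr, delay_days) {
  as.integer(hyperbolic_value(llr, k, delay_days) > ssr)
}

#' Candidate discount rates at indifference
#'
#' For every battery item with a positive delay, the k at which the
#' participant would be indifferent between the two rewards:
#' k = (LLR/SSR - 1)/D. Zero-delay items contribute no finite indifference
#' point and are skipped. Duplicates are collapsed and the grid sorted
#' ascending.
#'
#' @param battery Data frame from \code{\link{generate_battery}}.
#' @return Sorted numeric vector of unique candidate ks.
#' @export
candidate_k_grid <- function(battery) {
  pos <- battery[battery$delay_days > 0, , drop = FALSE]
  k <- (pos$llr / pos$ssr - 1) / pos$delay_days
  sort(unique(k))
}

#' Estimate a participant's discount rate (Kirby procedure)
#'
#' Scores every candidate k by the proportion of the participant's observed
#' choices it predicts under the shared strict-inequality comparator
#' (zero-delay items are included in match counting; every candidate
#' predicts the larger-later reward there). The best-matching k is
#' retained; when several candidates tie on match count, the geometric
#' mean of the full tied set is taken.
#'
#' @param responses Data frame for one participant with columns \code{ssr},
#'   \code{llr}, \code{delay_days} and \code{choice} (1 = larger-later,
#'   0 = smaller-sooner). Missing battery items are allowed (and counted
#'   against nothing); zero rows is an error.
#' @param grid Candidate ks, normally \code{\link{candidate_k_grid}} of the
#'   battery the responses came from. Defaults to the grid of the default
#'   battery.
#' @return One-row data frame of class \code{"discount_estimate"}:
#'   \code{k}, \code{log_k}, \code{match_prop}, \code{stochasticity}
#'   (\code{= 1 - match_prop}), \code{n_tied}, \code{n_items}.
#' @export
estimate_k <- function(responses, grid = candidate_k_grid(generate_battery())) {
  if (is.null(responses) || nrow(responses) == 0)
    stop("no responses for participant")
  stopifnot(all(responses$choice %in% c(0, 1)))
  full <- nrow(generate_battery())
  if (nrow(responses) < full)
    message("participant answered ", nrow(responses), " of ", full, " items")
  matches <- vapply(grid, function(k) {
    sum(predict_choice(k, responses$ssr, responses$llr,
                       responses$delay_days) == responses$choice)
  }, numeric(1))
  best <- max(matches)
  tied <- grid[matches == best]
  k_hat <- exp(mean(log(tied)))
  out <- data.frame(k = k_hat, log_k = log(k_hat),
                    match_prop = best / nrow(responses),
                    stochasticity = 1 - best / nrow(responses),
                    n_tied = length(tied), n_items = nrow(responses))
  class(out) <- c("discount_estimate", "data.frame")
  out
}

#' Fit discount rates for a table of participants
#'
#' Formula-free multi-participant wrapper around \code{\link{estimate_k}}.
#'
#' @param responses Data frame with columns \code{participant_id},
#'   \code{ssr}, \code{llr}, \code{delay_days} (or \code{delay_label},
#'   mapped through \code{delay_map}), \code{choice}.
#' @param battery Battery the responses came from (defines the candidate
#'   grid); default \code{\link{generate_battery}()}.
#' @param delay_map Used to fill \code{delay_days} from \code{delay_label}
#'   when absent.
#' @return Object of class \code{"discount_fit"}: a data frame with one row
#'   per participant (\code{participant_id}, \code{k}, \code{log_k},
#'   \code{match_prop}, \code{stochasticity}).
#' @export
fit_discount <- function(responses, battery = generate_battery(),
                         delay_map = default_delay_map()) {
  if (is.null(responses$delay_days)) {
    responses$delay_days <- unname(delay_map[responses$delay_label])
    if (any(is.na(responses$delay_days)))
      stop("unknown delay_label(s): ",
           paste(unique(responses$delay_label[is.na(responses$delay_days)]),
                 collapse = ", "))
  }
  if (is.null(responses$llr)) responses$llr <- battery$llr[1]
  grid <- candidate_k_grid(battery)
  parts <- split(responses, responses$participant_id)
  rows <- lapply(names(parts), function(pid) {
    est <- estimate_k(parts[[pid]], grid)
    cbind(participant_id = pid, est)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("discount_fit", "data.frame")
  out
}

#' @export
print.discount_fit <- function(x, ...) {
  cat(sprintf("Hyperbolic discounting fit: %d participant(s)\n", nrow(x)))
  cat(sprintf("  median k = %.4g, median log k = %.3f, mean match = %.3f\n",
              stats::median(x$k), stats::median(x$log_k),
              mean(x$match_prop)))
  invisible(x)
}

#' @export
coef.discount_fit <- function(object, ...) {
  stats::setNames(object$log_k, object$participant_id)
}

#' Attention check on same-day catch items
#'
#' Two catch items offer two present-time rewards of unequal value; a
#' participant fails if they ever choose the smaller one. With
#' \code{choice} coded 1 = larger reward, failure is any \code{choice == 0}
#' on a check item. If no check items are present the participant passes
#' with a warning.
#'
#' @param responses Data frame with a logical \code{is_check} column (or
#'   pass only the check rows) and \code{choice}.
#' @return \code{"pass"} or \code{"fail"}.
#' @export
attention_check <- function(responses) {
  checks <- if (!is.null(responses$is_check))
    responses[responses$is_check, , drop = FALSE] else responses
  if (nrow(checks) == 0) {
    warning("no attention-check items present; passing by default")
    return("pass")
  }
  if (nrow(checks) < 2)
    warning("only ", nrow(checks), " attention-check item(s) present")
  if (any(checks$choice == 0)) "fail" else "pass"
}
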