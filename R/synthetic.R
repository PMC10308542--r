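# Seeded generators for every input the pipeline consumes: labeled template
# sentences (with known time-reference and FTR-type ground truth), posts with
# temporal expressions planted at known day offsets, simulated intertemporal
# choosers with a known discount rate, and simulated participants following
# the two-equation mediation structure.

# Slot fillers. Deliberately free of every lexicon keyword so that the
# FTR-type ground truth is exactly what the template plants, and varied so
# the time-reference model cannot learn category keywords alone.
.subjects <- c("dog", "choir", "gardener", "band", "committee", "pilot",
               "team", "neighbour", "baker", "violinist")
.verbs <- data.frame(
  base = c("rain", "play", "jump", "walk", "cook", "paint", "climb",
           "travel", "sing", "dance"),
  s3 = c("rains", "plays", "jumps", "walks", "cooks", "paints", "climbs",
         "travels", "sings", "dances"),
  past = c("rained", "played", "jumped", "walked", "cooked", "painted",
           "climbed", "travelled", "sang", "danced"),
  stringsAsFactors = FALSE)
.places <- c("park", "valley", "kitchen", "stadium", "garden", "harbour",
             "meadow", "plaza", "orchard", "courtyard")
.adjs <- c("tall", "quiet", "green", "heavy", "bright", "narrow", "smooth",
           "ancient", "gentle", "crooked")

blank_flags <- function() {
  stats::setNames(as.list(rep(0L, length(.type_flags))), .type_flags)
}

sentence_templates <- function() {
  # Each entry: category name, true time_ref, flag setter, renderer(s, v, p).
  flag <- function(...) {
    f <- blank_flags()
    for (nm in c(...)) f[[nm]] <- 1L
    f
  }
  list(
    future_tense = list(
      time_ref = "FTR", flags = flag("future_tense"), excluded = "none",
      render = function(s, v, p)
        sprintf("Tomorrow the %s will %s in the %s.", s, v$base, p)),
    future_tense_going = list(
      time_ref = "FTR", flags = flag("future_tense"), excluded = "none",
      render = function(s, v, p)
        sprintf("The %s is going to %s near the %s tomorrow.", s, v$base, p)),
    present_tense = list(
      time_ref = "FTR", flags = flag("present_tense"), excluded = "none",
      render = function(s, v, p)
        sprintf("Tomorrow the %s %s at the %s.", s, v$s3, p)),
    verbal_low_certainty = list(
      time_ref = "FTR", flags = flag("verbal_low_certainty"),
      excluded = "none",
      render = function(s, v, p)
        sprintf("The %s could %s by the %s tomorrow.", s, v$base, p)),
    other_low_certainty = list(
      time_ref = "FTR", flags = flag("other_low_certainty"),
      excluded = "none",
      render = function(s, v, p)
        sprintf("The %s will probably %s at the %s tomorrow.", s, v$base, p)),
    other_high_certainty = list(
      time_ref = "FTR", flags = flag("other_high_certainty"),
      excluded = "none",
      render = function(s, v, p)
        sprintf("The %s will definitely %s beside the %s tomorrow.",
                s, v$base, p)),
    deontic = list(
      time_ref = "FTR", flags = flag("deontic"), excluded = "none",
      render = function(s, v, p)
        sprintf("The %s must %s across the %s tomorrow.", s, v$base, p)),
    bouletic = list(
      time_ref = "FTR", flags = flag("bouletic"), excluded = "none",
      render = function(s, v, p)
        sprintf("I hope the %s %s in the %s tomorrow.", s, v$s3, p)),
    irrealis = list(
      time_ref = "FTR", flags = flag("irrealis"), excluded = "none",
      render = function(s, v, p)
        sprintf("If the %s %s, the %s stays empty tomorrow.", s, v$s3, p)),
    concord = list(
      time_ref = "FTR",
      flags = flag("verbal_low_certainty", "other_low_certainty"),
      excluded = "none",
      render = function(s, v, p)
        sprintf("The %s could probably %s behind the %s tomorrow.",
                s, v$base, p)),
    negation_excluded = list(
      time_ref = "FTR", flags = blank_flags(), excluded = "negation",
      render = function(s, v, p)
        sprintf("The %s will not %s in the %s tomorrow.", s, v$base, p)),
    mixed_modal_excluded = list(
      time_ref = "FTR", flags = blank_flags(), excluded = "mixed_modal",
      render = function(s, v, p)
        sprintf("The %s could definitely %s at the %s tomorrow.",
                s, v$base, p)),
    ptr = list(
      time_ref = "PTR", flags = NULL, excluded = NA_character_,
      render = function(s, v, p)
        sprintf("The %s %s in the %s yesterday.", s, v$past, p)),
    other = list(
      time_ref = "OTHER", flags = NULL, excluded = NA_character_,
      render = function(s, v, p)
        sprintf("The %s in the %s is very %s.", s, p,
                .adjs[(nchar(p) %% length(.adjs)) + 1L]))
  )
}

#' Generate labeled template sentences
#'
#' Renders \code{n_per_category} sentences per template category by sampling
#' slot fillers (subject, verb, place). The FTR-type ground truth is known
#' by construction: templates are built from the shipped lexicon, so
#' \code{\link{classify_ftr_type}} agreeing with the planted flags is the
#' classifier's closure test. Categories cover all nine type flags, the
#' modal-concord case, both exclusion cases, plus PTR and OTHER sentences
#' for the time-reference stage. Deterministic per seed.
#'
#' @param n_per_category Sentences per category (>= 1).
#' @param seed Integer seed.
#' @return Data frame with \code{text}, \code{category}, \code{time_ref},
#'   the nine true type flags (NA for PTR/OTHER rows), \code{excluded},
#'   \code{exclusion_reason}, and \code{planted_offset} (days; +1 for
#'   tomorrow-anchored templates, -1 for yesterday, NA otherwise).
#' @export
generate_labeled_sentences <- function(n_per_category, seed = 1) {
  stopifnot(n_per_category >= 1)
  set.seed(as.integer(seed))
  tmpl <- sentence_templates()
  rows <- list()
  for (cat in names(tmpl)) {
    t <- tmpl[[cat]]
    for (r in seq_len(n_per_category)) {
      s <- sample(.subjects, 1)
      v <- .verbs[sample.int(nrow(.verbs), 1), ]
      p <- sample(.places, 1)
      txt <- t$render(s, v, p)
      fl <- if (is.null(t$flags))
        stats::setNames(as.list(rep(NA_integer_, length(.type_flags))),
                        .type_flags) else t$flags
      offset <- if (grepl("tomorrow", txt, ignore.case = TRUE)) 1L
        else if (grepl("yesterday", txt, ignore.case = TRUE)) -1L
        else NA_integer_
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(text = txt, category = cat, time_ref = t$time_ref,
                   stringsAsFactors = FALSE),
        as.data.frame(fl),
        data.frame(excluded = if (is.na(t$excluded)) NA_integer_
                   else as.integer(t$excluded != "none"),
                   exclusion_reason = t$excluded,
                   planted_offset = offset, stringsAsFactors = FALSE))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Annotated examples for time-reference training
#'
#' Repackages \code{\link{generate_labeled_sentences}} output as annotated
#' examples (\code{text}, \code{target_label}, \code{decision = "accept"})
#' for \code{\link{train_time_reference}}.
#'
#' @inheritParams generate_labeled_sentences
#' @return Data frame of annotated examples.
#' @export
generate_training_examples <- function(n_per_category, seed = 1) {
  corp <- generate_labeled_sentences(n_per_category, seed)
  data.frame(text = corp$text, target_label = corp$time_ref,
             decision = "accept", stringsAsFactors = FALSE)
}

offset_surface <- function(off) {
  if (off == 0) return("today")
  if (off == 1) return("tomorrow")
  if (off == -1) return("yesterday")
  if (off > 1) return(sprintf("in %d days", off))
  sprintf("%d days ago", -off)
}

#' Generate posts with temporal expressions at known offsets
#'
#' Each post is a single sentence embedding one surface expression per
#' requested day offset, so the horizon pipeline must recover the planted
#' mean exactly. Anchors are seeded random dates in 2020, with posting time
#' fixed at midnight UTC so that planted zero offsets are not mistaken for
#' midnight-anchoring artifacts.
#'
#' @param n Number of posts.
#' @param offsets Integer day offsets planted in every post (e.g.
#'   \code{c(2, 4)} plants "in 2 days" and "in 4 days"; mean horizon 3).
#' @param seed Integer seed.
#' @param condition Condition label for the posts.
#' @return Data frame of posts (\code{post_id}, \code{author_id},
#'   \code{text}, \code{posted_at}, \code{condition}) with the planted
#'   per-post mean in column \code{planted_mean}.
#' @export
generate_timed_posts <- function(n, offsets, seed = 1,
                                 condition = "unlabeled") {
  if (any(is.na(offsets)) || any(offsets != round(offsets)))
    stop("offsets must be whole numbers of days")
  offsets <- as.integer(offsets)
  stopifnot(n >= 1, length(offsets) >= 1)
  set.seed(as.integer(seed))
  anchors <- as.Date("2020-01-01") + sample.int(300, n, replace = TRUE)
  rows <- lapply(seq_len(n), function(i) {
    s <- sample(.subjects, 1)
    parts <- vapply(offsets, offset_surface, character(1))
    txt <- sprintf("The %s event is %s.", s,
                   paste(parts, collapse = " and then "))
    data.frame(post_id = sprintf("post%04d", i),
               author_id = sprintf("author%03d", ((i - 1) %% 97) + 1),
               text = txt,
               posted_at = as.POSIXct(paste(anchors[i], "00:00:00"),
                                      tz = "UTC"),
               condition = condition,
               planted_mean = mean(offsets), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate one participant's intertemporal choices
#'
#' Deterministic choices under \code{k_true} with the shared
#' strict-inequality comparator (larger-later chosen iff its hyperbolically
#' discounted value strictly exceeds the immediate amount), then each
#' choice independently flipped with probability \code{epsilon}.
#'
#' @param k_true True discount rate (> 0).
#' @param epsilon Flip probability in [0, 0.5).
#' @param seed Integer seed.
#' @param battery Battery data frame (default the full 110-item battery).
#' @param participant_id Identifier for the output rows.
#' @return Data frame: battery columns plus \code{participant_id} and
#'   \code{choice}.
#' @export
simulate_choices <- function(k_true, epsilon = 0, seed = 1,
                             battery = generate_battery(),
                             participant_id = "p1") {
  stopifnot(k_true > 0, epsilon >= 0, epsilon < 0.5)
  set.seed(as.integer(seed))
  choice <- predict_choice(k_true, battery$ssr, battery$llr,
                           battery$delay_days)
  flip <- stats::runif(length(choice)) < epsilon
  choice[flip] <- 1L - choice[flip]
  cbind(participant_id = participant_id, battery,
        choice = choice, stringsAsFactors = FALSE)
}

#' Simulate participants with a planted mediation structure
#'
#' DASS-like anxiety and depression scores are produced by discretising a
#' latent bivariate normal (correlation \code{rho}) to the 0-42 range; the
#' mediator and outcome then follow the two planted linear equations with
#' Gaussian noise:
#' \deqn{M = \lambda_1 + \alpha_1 anx + \alpha_2 dep + e_1}
#' \deqn{Y = \lambda_2 + \tau'_1 anx + \tau'_2 dep + \beta M + e_2}
#'
#' Defaults plant an anxiety-driven mediation (indirect effect
#' \eqn{\alpha_1 \beta \approx 0.04}, total \eqn{\approx 0.08}) with a
#' negligible depression effect, at the sample size and score
#' distributions typical of an online survey of ~200 UK adults.
#'
#' @param n Number of participants (>= 2).
#' @param alpha1,alpha2 Paths anxiety -> M and depression -> M.
#' @param beta Path M -> Y.
#' @param tau1,tau2 Direct paths anxiety -> Y and depression -> Y.
#' @param rho Latent anxiety-depression correlation in (-1, 1).
#' @param sd_m,sd_y Gaussian noise SDs for the two equations.
#' @param lambda1,lambda2 Intercepts.
#' @param mean_anx,sd_anx,mean_dep,sd_dep Latent score moments before
#'   discretisation.
#' @param seed Integer seed.
#' @return Data frame: \code{participant_id}, \code{anxiety},
#'   \code{depression}, \code{mean_subj_dist}, \code{log_k}.
#' @export
simulate_study2 <- function(n = 202, alpha1 = 0.9, alpha2 = 0.15,
                            beta = 0.045, tau1 = 0.04, tau2 = -0.01,
                            rho = 0.6, sd_m = 14, sd_y = 2.1,
                            lambda1 = 28.25, lambda2 = -4.41,
                            mean_anx = 4.4, sd_anx = 7.07,
                            mean_dep = 6.86, sd_dep = 9.66, seed = 1) {
  stopifnot(n >= 2, rho > -1, rho < 1)
  set.seed(as.integer(seed))
  Sigma <- matrix(c(sd_anx^2, rho * sd_anx * sd_dep,
                    rho * sd_anx * sd_dep, sd_dep^2), 2, 2)
  lat <- MASS::mvrnorm(n, mu = c(mean_anx, mean_dep), Sigma = Sigma)
  clamp <- function(x) pmin(pmax(round(x / 2) * 2, 0), 42)  # even DASS scores
  anx <- clamp(lat[, 1])
  dep <- clamp(lat[, 2])
  M <- lambda1 + alpha1 * anx + alpha2 * dep + stats::rnorm(n, 0, sd_m)
  Y <- lambda2 + tau1 * anx + tau2 * dep + beta * M + stats::rnorm(n, 0, sd_y)
  data.frame(participant_id = sprintf("p%04d", seq_len(n)),
             anxiety = anx, depression = dep,
             mean_subj_dist = M, log_k = Y, stringsAsFactors = FALSE)
}
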