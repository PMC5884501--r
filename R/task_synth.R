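#' Longest right-aligned suffix match
#'
#' The answer rule of the number-search task: each question shows a 7-digit
#' target and several shorter comparison numbers; the correct answer is the
#' length of the longest comparison that equals the target's suffix when
#' right-aligned. Returns 0 when no comparison matches.
#'
#' @param target a 7-character digit string.
#' @param comparisons character vector of digit strings (lengths 2..5).
#' @return Integer: the longest matching length, or 0.
#' @examples
#' longest_suffix_match("3402436", c("02436", "2436", "436", "36"))  # 5
#' @export
longest_suffix_match <- function(target, comparisons) {
  if (!grepl("^[0-9]{7}$", target))
    stop("target must be a 7-digit string")
  if (any(!grepl("^[0-9]{2,5}$", comparisons)))
    stop("comparisons must be digit strings of length 2..5")
  lens <- nchar(comparisons)
  hit <- vapply(seq_along(comparisons), function(i) {
    substring(target, 8 - lens[i], 7) == comparisons[i]
  }, logical(1))
  if (!any(hit)) return(0L)
  as.integer(max(lens[hit]))
}

# Fixed screen template for the 1920x1080 question page: target centred at
# the top, comparisons in two columns, five answer options in a bottom row.
layout_template <- function() {
  comp_x <- c(660, 1260)
  comp_y <- c(330, 450, 570, 690)
  slots <- expand.grid(y = comp_y, x = comp_x)[, c("x", "y")]
  list(
    target = c(cx = 960, cy = 150, w = 360, h = 90),
    comparison_slots = data.frame(cx = slots$x, cy = slots$y, w = 240, h = 70),
    options = data.frame(label = 1:5,
                         cx = c(320, 640, 960, 1280, 1600),
                         cy = 930, w = 220, h = 80))
}

rect_from <- function(cx, cy, w, h) {
  data.frame(x0 = cx - w / 2, y0 = cy - h / 2, x1 = cx + w / 2, y1 = cy + h / 2)
}

random_digits <- function(n) paste(sample(0:9, n, replace = TRUE), collapse = "")

#' Generate a number-search question layout
#'
#' Builds a random question satisfying the task's answer rule: the target's
#' suffixes of lengths `2..correct_answer` appear as comparisons (one per
#' length), all remaining comparison slots are filled with non-matching
#' decoys, and no comparison longer than `correct_answer` matches. Five
#' answer-option boxes are labelled 1..5; the correct label always lies in
#' 2..5, so guessing succeeds with probability 1/5.
#'
#' @param correct_answer integer in 2..5, the intended answer length.
#' @param seed integer seed; layouts are deterministic per seed.
#' @param n_comparisons number of comparison numbers shown (5..8).
#' @return An object of class `question_layout` with fields `target`,
#'   `comparisons` (text + rectangle + match flag), `options`,
#'   `correct_answer` and region centres used by the simulator.
#' @export
make_layout <- function(correct_answer, seed = 1L, n_comparisons = 8L) {
  stopifnot(correct_answer %in% 2:5, n_comparisons >= 5, n_comparisons <= 8)
  tpl <- layout_template()
  with_seed(seed, {
    target <- random_digits(7)
    match_lens <- 2:correct_answer
    texts <- vapply(match_lens, function(L) substring(target, 8 - L, 7),
                    character(1))
    n_decoys <- n_comparisons - length(texts)
    decoy_lens <- rep_len(2:5, n_decoys)
    decoys <- vapply(decoy_lens, function(L) {
      repeat {
        d <- random_digits(L)
        if (d != substring(target, 8 - L, 7)) return(d)
      }
    }, character(1))
    all_texts <- c(texts, decoys)
    is_match <- c(rep(TRUE, length(texts)), rep(FALSE, n_decoys))
    ord <- sample(n_comparisons)
    slots <- tpl$comparison_slots[seq_len(n_comparisons), , drop = FALSE]
    comp <- cbind(data.frame(text = all_texts[ord], matches = is_match[ord],
                             stringsAsFactors = FALSE),
                  rect_from(slots$cx, slots$cy, slots$w, slots$h),
                  data.frame(cx = slots$cx, cy = slots$cy))
    opts <- cbind(tpl$options["label"],
                  rect_from(tpl$options$cx, tpl$options$cy,
                            tpl$options$w, tpl$options$h),
                  tpl$options[c("cx", "cy")])
    structure(
      list(target = target,
           target_rect = cbind(rect_from(tpl$target["cx"], tpl$target["cy"],
                                         tpl$target["w"], tpl$target["h"]),
                               data.frame(cx = tpl$target[["cx"]],
                                          cy = tpl$target[["cy"]])),
           comparisons = comp, options = opts,
           correct_answer = as.integer(correct_answer)),
      class = "question_layout")
  })
}

#' @export
print.question_layout <- function(x, ...) {
  cat(sprintf("<question_layout> target %s, %d comparisons, answer %d\n",
              x$target, nrow(x$comparisons), x$correct_answer))
  invisible(x)
}

default_profile_population <- function() {
  list(fix_shape = 4, fix_scale = 0.0625,     # Gamma fixation durations, mean 250 ms
       sacc_slope = 2.2, sacc_intercept = 21, # main sequence, ms per deg / ms
       drift_sd = 0.10, tremor_sd = 0.05,     # within-fixation drift / sample noise, deg
       landing_gain = 0.95,                   # saccadic gain (slight undershoot)
       revisit = 0.3)                         # probability of re-checking the target
}

#' Draw a cohort of per-subject oculomotor profiles
#'
#' Subjects differ in fixation-duration Gamma parameters, saccade
#' main-sequence parameters, within-fixation drift and tremor magnitudes,
#' saccadic landing gain (habitual under/overshoot), region-visit
#' preferences and target-revisit probability. Between-subject spread is
#' controlled by `separation`: parameters are population values multiplied
#' by log-normal factors with log-sd `separation * cv`, so
#' `separation = 0` yields identical profiles and `separation = 1` a
#' clearly separable cohort (between-subject variance exceeding
#' within-session noise). The per-parameter spreads put most of the
#' idiosyncrasy into *where* the gaze goes (scan preferences, revisits,
#' landing accuracy) and keep gross temporal scales (durations, speeds)
#' only mildly subject-specific, matching the premise that the spatial
#' arrangement of a trajectory — not the amount of trace drawn — carries
#' the identity signal.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param seed integer seed.
#' @param separation non-negative separability knob (default 1).
#' @return A list of `oculomotor_profile` objects.
#' @export
make_cohort <- function(n_subjects, seed = 1L, separation = 1) {
  if (n_subjects < 2) stop("a cohort needs at least 2 subjects")
  stopifnot(separation >= 0)
  pop <- default_profile_population()
  cv <- c(fix_shape = 0.10, fix_scale = 0.10, sacc_slope = 0.12,
          sacc_intercept = 0.12, drift_sd = 0.20, tremor_sd = 0.20,
          landing_gain = 0.08)
  with_seed(seed, {
    lapply(seq_len(n_subjects), function(i) {
      fac <- exp(rnorm(length(cv), 0, separation * cv))
      names(fac) <- names(cv)
      p <- pop
      for (nm in names(cv)) p[[nm]] <- p[[nm]] * fac[[nm]]
      p$revisit <- stats::plogis(stats::qlogis(pop$revisit) +
                                   rnorm(1, 0, separation * 0.3))
      w <- exp(rnorm(8, 0, separation))
      p$scan_bias <- w / sum(w)
      p$subject_id <- sprintf("S%02d", i)
      structure(p, class = "oculomotor_profile")
    })
  })
}

min_jerk <- function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5

# AR(1) (discretized Ornstein-Uhlenbeck) positional drift about an anchor.
ou_drift <- function(n, anchor, sd_px, rate_hz, tau_s = 0.1) {
  if (sd_px == 0 || n == 0) return(rep(anchor, n))
  rho <- exp(-1 / (rate_hz * tau_s))
  innov_sd <- sd_px * sqrt(1 - rho^2)
  p <- numeric(n)
  p[1] <- anchor + rnorm(1, 0, sd_px)
  if (n > 1) for (i in 2:n)
    p[i] <- anchor + rho * (p[i - 1] - anchor) + rnorm(1, 0, innov_sd)
  p
}

#' Simulate the gaze recording of one question
#'
#' Emulates a subject solving one number-search question: the gaze
#' alternates between fixations (anchored near region centres with
#' Ornstein-Uhlenbeck drift plus Gaussian tremor, durations Gamma
#' distributed per the subject's profile) and saccades (straight paths with
#' a minimum-jerk velocity profile whose duration follows the linear
#' amplitude-duration main sequence). Comparison regions are visited in an
#' order biased by the profile's `scan_bias`; the target is re-checked with
#' the profile's revisit probability; the trial ends on the correct answer
#' option with probability `accuracy`, else on a random other option.
#'
#' @param profile an `oculomotor_profile` from [make_cohort()].
#' @param layout a [make_layout()] question.
#' @param rate_hz sampling rate in Hz (>= 30).
#' @param geometry a [screen_geometry()].
#' @param seed integer seed; recordings are deterministic per seed.
#' @param accuracy probability of answering correctly.
#' @param dropout per-sample probability of an invalid (lost) sample.
#' @return A [gaze_recording()]; attributes `events` (ground-truth event
#'   table with analytic saccade peak velocities) and `answer_correct`.
#' @export
simulate_question <- function(profile, layout, rate_hz = 300,
                              geometry = screen_geometry(), seed = 1L,
                              accuracy = 0.9, dropout = 0) {
  stopifnot(inherits(profile, "oculomotor_profile"),
            inherits(layout, "question_layout"), rate_hz >= 30)
  if (geometry$width_px <= 1 || geometry$height_px <= 1)
    stop("degenerate screen geometry")
  drift_px <- degrees_to_pixels(geometry, profile$drift_sd)
  tremor_px <- degrees_to_pixels(geometry, profile$tremor_sd)
  with_seed(seed, {
    ncomp <- nrow(layout$comparisons)
    # question-to-question strategy fluctuation (attentional state noise):
    # the habitual revisit rate and scan preferences are jittered per
    # question, so strategy is a noisy subject trait, not a fixed stamp
    rev_q <- stats::plogis(stats::qlogis(profile$revisit) + rnorm(1, 0, 0.5))
    bias <- profile$scan_bias[seq_len(ncomp)] * exp(rnorm(ncomp, 0, 0.5))
    comp_order <- sample.int(ncomp, ncomp, prob = bias / sum(bias))
    centers <- list(c(layout$target_rect$cx, layout$target_rect$cy))
    for (ci in comp_order) {
      centers <- c(centers, list(c(layout$comparisons$cx[ci],
                                   layout$comparisons$cy[ci])))
      if (runif(1) < rev_q)
        centers <- c(centers, list(c(layout$target_rect$cx,
                                     layout$target_rect$cy)))
    }
    correct <- runif(1) < accuracy
    lbl <- if (correct) layout$correct_answer else
      sample(setdiff(layout$options$label, layout$correct_answer), 1)
    oi <- match(lbl, layout$options$label)
    centers <- c(centers, list(c(layout$options$cx[oi], layout$options$cy[oi])))

    xs <- numeric(0); ys <- numeric(0)
    ev_type <- character(0); ev_dur <- numeric(0)
    ev_amp <- numeric(0); ev_peak <- numeric(0)
    gain <- if (is.null(profile$landing_gain)) 1 else profile$landing_gain
    for (r in seq_along(centers)) {
      anchor <- centers[[r]] + rnorm(2, 0, drift_px)
      if (r > 1) {  # saccade from the current gaze position towards the
                    # new anchor, landing short/long per the subject's gain
        from <- c(xs[length(xs)], ys[length(ys)])
        anchor <- from + gain * (anchor - from)
        amp_px <- sqrt(sum((anchor - from)^2))
        amp_deg <- pixels_to_degrees(geometry, amp_px)
        dur_s <- (profile$sacc_intercept + profile$sacc_slope * amp_deg) / 1000
        n_sac <- max(1L, as.integer(round(dur_s * rate_hz)))
        tau <- seq_len(n_sac) / (n_sac + 1)
        s <- min_jerk(tau)
        xs <- c(xs, from[1] + (anchor[1] - from[1]) * s)
        ys <- c(ys, from[2] + (anchor[2] - from[2]) * s)
        ev_type <- c(ev_type, "saccade"); ev_dur <- c(ev_dur, dur_s)
        ev_amp <- c(ev_amp, amp_deg)
        ev_peak <- c(ev_peak, 1.875 * amp_deg / dur_s)
      }
      fdur <- rgamma(1, shape = profile$fix_shape, scale = profile$fix_scale)
      n_fix <- max(2L, as.integer(round(fdur * rate_hz)))
      xs <- c(xs, ou_drift(n_fix, anchor[1], drift_px * 0.5, rate_hz))
      ys <- c(ys, ou_drift(n_fix, anchor[2], drift_px * 0.5, rate_hz))
      ev_type <- c(ev_type, "fixation"); ev_dur <- c(ev_dur, n_fix / rate_hz)
      ev_amp <- c(ev_amp, NA_real_); ev_peak <- c(ev_peak, NA_real_)
    }
    n <- length(xs)
    if (tremor_px > 0) {
      xs <- xs + rnorm(n, 0, tremor_px)
      ys <- ys + rnorm(n, 0, tremor_px)
    }
    valid <- runif(n) >= dropout
    if (sum(valid) < 2) valid[1:2] <- TRUE
    rec <- gaze_recording(t = (seq_len(n) - 1) / rate_hz, x = xs, y = ys,
                          valid = valid, rate_hz = rate_hz,
                          subject_id = profile$subject_id)
    attr(rec, "events") <- data.frame(type = ev_type, duration = ev_dur,
                                      amplitude_deg = ev_amp,
                                      peak_velocity_deg_s = ev_peak)
    attr(rec, "answer_correct") <- correct
    rec
  })
}

#' Session plan
#'
#' Bookkeeping for a data-collection campaign: subjects x trials x tests x
#' questions. The default mirrors a two-visit study of 58 subjects with 4
#' tests of 40 questions per trial, i.e. 320 recordings per subject and
#' 18,560 in total.
#'
#' @param n_subjects,n_trials,tests_per_trial,questions_per_test positive
#'   integers.
#' @param rate_hz sampling rate.
#' @param seed integer seed for the whole session.
#' @return A `session_plan` list.
#' @export
session_plan <- function(n_subjects = 58, n_trials = 2, tests_per_trial = 4,
                         questions_per_test = 40, rate_hz = 300, seed = 1L) {
  stopifnot(n_subjects >= 1, n_trials >= 1, tests_per_trial >= 1,
            questions_per_test >= 1)
  structure(list(n_subjects = as.integer(n_subjects),
                 n_trials = as.integer(n_trials),
                 tests_per_trial = as.integer(tests_per_trial),
                 questions_per_test = as.integer(questions_per_test),
                 rate_hz = rate_hz, seed = as.integer(seed)),
            class = "session_plan")
}

#' Total number of recordings implied by a session plan
#' @param plan a [session_plan()].
#' @return Integer count `n_subjects * n_trials * tests_per_trial *
#'   questions_per_test`.
#' @export
session_size <- function(plan) {
  stopifnot(inherits(plan, "session_plan"))
  plan$n_subjects * plan$n_trials * plan$tests_per_trial *
    plan$questions_per_test
}

# Multiplicative jitter of a profile's parameters, emulating template aging
# between trials (fatigue, practice, uncontrolled state changes).
perturb_profile <- function(profile, aging_sd, seed) {
  if (aging_sd == 0) return(profile)
  with_seed(seed, {
    p <- profile
    for (nm in c("fix_shape", "fix_scale", "sacc_slope", "sacc_intercept",
                 "drift_sd", "tremor_sd", "landing_gain"))
      p[[nm]] <- profile[[nm]] * abs(rnorm(1, 1, aging_sd))
    p$revisit <- min(1, profile$revisit * abs(rnorm(1, 1, aging_sd)))
    w <- profile$scan_bias * exp(rnorm(length(profile$scan_bias), 0, aging_sd))
    p$scan_bias <- w / sum(w)
    p
  })
}

#' Simulate a full data-collection session
#'
#' Generates every recording of a [session_plan()]: a cohort of subjects
#' (see [make_cohort()]) answers a shared set of question layouts (balanced
#' over the four answer kinds). Recordings in trial 2 are simulated from
#' profiles perturbed by multiplicative Gaussian jitter of sd `aging_sd`,
#' emulating template aging across the inter-trial interval; `aging_sd = 0`
#' makes both trials statistically identical.
#'
#' @param plan a [session_plan()].
#' @param geometry a [screen_geometry()].
#' @param separation cohort separability knob, see [make_cohort()].
#' @param aging_sd trial-2 profile jitter (fractional sd).
#' @param accuracy probability of a correct answer per question.
#' @param dropout per-sample invalidity probability.
#' @return A list with `recordings` (list of [gaze_recording()]s),
#'   `summary` (per subject x trial mean reaction time and accuracy rate)
#'   and the `plan`.
#' @export
simulate_session <- function(plan, geometry = screen_geometry(),
                             separation = 1, aging_sd = 0, accuracy = 0.9,
                             dropout = 0) {
  stopifnot(inherits(plan, "session_plan"))
  n_q <- plan$tests_per_trial * plan$questions_per_test
  kinds <- rep_len(2:5, n_q)
  layouts <- lapply(seq_len(n_q), function(q)
    make_layout(kinds[q], seed = derive_seed(plan$seed, paste0("layout", q))))
  cohort <- make_cohort(plan$n_subjects, derive_seed(plan$seed, "cohort"),
                        separation)
  recordings <- vector("list", session_size(plan))
  summary_rows <- list()
  idx <- 1L
  for (s in seq_len(plan$n_subjects)) {
    for (tr in seq_len(plan$n_trials)) {
      prof <- if (tr == 1) cohort[[s]] else
        perturb_profile(cohort[[s]], aging_sd,
                        derive_seed(plan$seed, paste0("aging", s)))
      rts <- numeric(n_q); ok <- logical(n_q)
      for (q in seq_len(n_q)) {
        rec <- simulate_question(
          prof, layouts[[q]], rate_hz = plan$rate_hz, geometry = geometry,
          seed = derive_seed(plan$seed, sprintf("rec_%d_%d_%d", s, tr, q)),
          accuracy = accuracy, dropout = dropout)
        rec$question_id <- sprintf("q%03d", q)
        rec$trial <- tr
        rts[q] <- max(rec$samples$t)
        ok[q] <- attr(rec, "answer_correct")
        recordings[[idx]] <- rec
        idx <- idx + 1L
      }
      summary_rows[[length(summary_rows) + 1L]] <-
        data.frame(subject = prof$subject_id, trial = tr,
                   mean_rt = mean(rts), accuracy = mean(ok))
    }
  }
  list(recordings = recordings, summary = do.call(rbind, summary_rows),
       plan = plan)
}
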