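## Synthetic cohort generator: emulates the block/trial design, the
## condition-dependent rotation trajectories, the word timing, and the
## psychometrically generated word responses of the self-rotation speech
## test, including an injectable dynamic-motion deficit.

#' Configuration of a synthetic cohort
#'
#' Defaults reproduce the experiment's conditions: 9 participants, 6
#' blocks of 48 trials (12 per target location), target onset 1 s after a
#' 4.5 s interferer, sentence durations with mean 2.19 s truncated to
#' [1.78, 2.77] s, head tracking at 358.6 Hz, natural fast turns capped at
#' 150 deg/s, condition-dependent undershoot of the target azimuth, and a
#' logistic psychometric truth with maximum slope 0.08 per dB.
#'
#' @param n_participants number of participants (default 9).
#' @param seed integer RNG seed recorded in the config and used by
#'   [gen_cohort()].
#' @param beta0 psychometric intercept on the logit scale.
#' @param beta1 psychometric slope per dB on the logit scale (the maximum
#'   slope in proportion/dB is `beta1 / 4`; default 0.32 -> 0.08/dB).
#' @param sigma_u SD of the per-participant random intercept.
#' @param delta dynamic-motion deficit in dB (default 1.4), subtracted
#'   from the predicted benefit of words spoken while the head moves.
#' @param delta_mode `"word_gated"` (default) applies `delta` to words
#'   whose window RMS angular speed exceeds `motion_threshold`;
#'   `"trial_constant"` applies it to every word of moving-condition
#'   trials.
#' @param motion_threshold RMS angular speed gate in deg/s (default 5).
#' @param reaction_mean,reaction_sd reaction time (s) after target onset
#'   before the main turn.
#' @param peak_speed angular speed cap in deg/s (default 150).
#' @param min_turn_duration shortest main-turn duration in s.
#' @param undershoot named list of mean final-orientation offsets (deg)
#'   per condition: `frontal` (signed offset from 0), `lateral`
#'   (undershoot magnitude from 90) and `rear` (undershoot magnitude from
#'   180), each c(AV = ..., `A-only` = ...); defaults are the observed
#'   final-word medians.
#' @param undershoot_sd per-condition SD (deg) of the final orientation,
#'   c(AV, `A-only`); the smaller AV spread mirrors the observed tighter
#'   AV distributions.
#' @param sentence_mean,sentence_sd,sentence_range truncated-normal
#'   sentence-duration model (s); the location parameter is solved so the
#'   truncated mean equals `sentence_mean`.
#' @param word_alpha Dirichlet concentration of the five word-duration
#'   proportions.
#' @param track_rate head-tracking rate in Hz.
#' @param interferer_duration,target_onset interferer length and target
#'   onset time (s).
#' @param static_predictions named numeric: model-predicted spatial
#'   unmasking (dB re the co-located configuration) per target azimuth at
#'   yaw 0; used as the psychometric predictor when no benefit maps are
#'   supplied (Static-only cohorts). Defaults are the benefit-map values
#'   at yaw 0 in the default room.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 9, seed = 1,
                          beta0 = -0.5, beta1 = 0.32, sigma_u = 0.4,
                          delta = 1.4,
                          delta_mode = c("word_gated", "trial_constant"),
                          motion_threshold = 5,
                          reaction_mean = 0.25, reaction_sd = 0.08,
                          peak_speed = 150, min_turn_duration = 0.4,
                          undershoot = list(
                            frontal = c(AV = -0.5, `A-only` = -11.5),
                            lateral = c(AV = 27.4, `A-only` = 29),
                            rear = c(AV = 49.4, `A-only` = 74.1)),
                          undershoot_sd = c(AV = 10, `A-only` = 20),
                          sentence_mean = 2.19, sentence_sd = 0.2,
                          sentence_range = c(1.78, 2.77),
                          word_alpha = 8, track_rate = 358.6,
                          interferer_duration = 4.5, target_onset = 1,
                          static_predictions = STATIC_PREDICTIONS) {
  delta_mode <- match.arg(delta_mode)
  stopifnot(sigma_u >= 0, delta >= 0, peak_speed > 0, reaction_sd >= 0,
            sentence_sd >= 0, all(undershoot_sd >= 0))
  ## location parameter giving the requested truncated mean
  mu <- uniroot(function(m)
    truncnorm_mean(m, sentence_sd, sentence_range[1], sentence_range[2]) -
      sentence_mean,
    interval = sentence_mean + c(-1, 1))$root
  structure(list(
    n_participants = n_participants, seed = seed,
    beta0 = beta0, beta1 = beta1, sigma_u = sigma_u,
    delta = delta, delta_mode = delta_mode,
    motion_threshold = motion_threshold,
    reaction_mean = reaction_mean, reaction_sd = reaction_sd,
    peak_speed = peak_speed, min_turn_duration = min_turn_duration,
    undershoot = undershoot, undershoot_sd = undershoot_sd,
    sentence_mean = sentence_mean, sentence_sd = sentence_sd,
    sentence_mu = mu, sentence_range = sentence_range,
    word_alpha = word_alpha, track_rate = track_rate,
    interferer_duration = interferer_duration,
    target_onset = target_onset,
    targets = c(0, -90, 90, 180), conditions = c("Static", "A-only", "AV"),
    static_predictions = static_predictions),
    class = "cohort_config")
}

#' Block/trial design for one participant
#'
#' Six blocks of 48 trials with the condition fixed per block: each of the
#' three conditions appears in exactly two blocks, the first three blocks
#' cover all three conditions, and every block presents each of the four
#' target locations exactly 12 times in pseudo-random order.
#'
#' @param config a [cohort_config()].
#' @return data.frame with columns `block`, `trial`, `condition`,
#'   `target`.
#' @export
make_design <- function(config) {
  conds <- c(sample(config$conditions), sample(config$conditions))
  do.call(rbind, lapply(1:6, function(b) {
    data.frame(block = b, trial = seq_len(48), condition = conds[b],
               target = sample(rep(config$targets, each = 12)))
  }))
}

#' Draw word windows for one sentence
#'
#' Sentence duration is a truncated normal within the configured range
#' (location solved so the truncated mean matches the configured mean);
#' the five word windows partition the sentence with Dirichlet-distributed
#' proportions, starting at the target onset.
#'
#' @param config a [cohort_config()].
#' @return a [word_windows()].
#' @export
gen_word_windows <- function(config) {
  dur <- rtruncnorm1(1, config$sentence_mu, config$sentence_sd,
                     config$sentence_range[1], config$sentence_range[2])
  prop <- rdirichlet1(rep(config$word_alpha, 5))
  edges <- config$target_onset + c(0, cumsum(prop)) * dur
  word_windows(onsets = edges[1:5], offsets = edges[2:6])
}

## Minimum-jerk position profile from 0 to 1 over s in [0, 1].
min_jerk <- function(s) {
  s <- pmin(1, pmax(0, s))
  10 * s^3 - 15 * s^4 + 6 * s^5
}

## Smooth low-amplitude postural sway (deg): a few sub-Hz sinusoids with
## random frequency and phase, |jitter| <= cap and slow enough that its
## RMS angular speed stays well below the motion gate.
smooth_jitter <- function(n, rate, sd_deg = 0.6, cap = 2.9) {
  t <- (seq_len(n) - 1) / rate
  x <- numeric(n)
  for (i in 1:3) {
    f <- runif(1, 0.05, 0.35)
    x <- x + runif(1, 0.5, 1) * sin(2 * pi * f * t + runif(1, 0, 2 * pi))
  }
  x <- x - x[1]
  s <- stats::sd(x)
  if (is.na(s) || s == 0) return(numeric(n))
  pmin(cap, pmax(-cap, x * sd_deg / s))
}

#' Generate one head-yaw trajectory
#'
#' Static trials hold the frontal orientation with small postural jitter
#' (within the 3 deg tolerance). Moving trials hold until a reaction time
#' after target onset, then execute a minimum-jerk turn toward the target
#' minus a condition-dependent undershoot (rear targets go left or right
#' with equal probability), with the peak angular speed capped, followed
#' by a small overshoot-and-correct phase.
#'
#' @param condition `"Static"`, `"A-only"` or `"AV"`.
#' @param target target azimuth in degrees (0, -90, 90, 180).
#' @param config a [cohort_config()].
#' @param participant,trial identifiers forwarded to [trajectory()].
#' @return a [trajectory()] spanning the interferer duration.
#' @export
gen_trajectory <- function(condition, target, config,
                           participant = NA, trial = NA) {
  n <- ceiling(config$interferer_duration * config$track_rate) + 1
  t <- (seq_len(n) - 1) / config$track_rate
  jit <- smooth_jitter(n, config$track_rate)
  if (condition == "Static")
    return(trajectory(t, jit, participant, trial))

  sdv <- config$undershoot_sd[[condition]]
  goal <- if (target == 0) {
    rnorm(1, config$undershoot$frontal[[condition]], sdv)
  } else if (abs(target) == 90) {
    u <- rnorm(1, config$undershoot$lateral[[condition]], sdv)
    sign(target) * (90 - u)
  } else {
    side <- sample(c(-1, 1), 1)
    u <- rnorm(1, config$undershoot$rear[[condition]], sdv)
    side * (180 - u)
  }
  rt <- config$target_onset +
    max(0.05, rnorm(1, config$reaction_mean, config$reaction_sd))
  over <- sign(goal) * max(0, rnorm(1, 6, 2))
  ## duration set by the speed cap on the full first-segment amplitude
  turn_t <- max(config$min_turn_duration,
                1.875 * abs(goal + over) / config$peak_speed)
  corr_t <- 0.5
  yaw <- numeric(n)
  s1 <- (t - rt) / turn_t
  yaw <- (goal + over) * min_jerk(s1)
  s2 <- (t - rt - turn_t) / corr_t
  yaw <- yaw - over * min_jerk(s2)
  trajectory(t, yaw + 0.3 * jit, participant, trial)
}

## RMS angular speed (deg/s) of a trajectory within a time window.
window_rms_speed <- function(traj, onset, offset) {
  sel <- traj$time >= onset & traj$time < offset
  if (sum(sel) < 2) return(0)
  v <- diff(traj$yaw[sel]) * traj$rate
  sqrt(mean(v^2))
}

#' Generate the five word-correct flags of one trial
#'
#' Per word, the effective benefit is the predicted dB minus the
#' dynamic-motion deficit `delta` when the word-window RMS angular speed
#' exceeds the motion threshold (or for all words of a moving-condition
#' trial in `"trial_constant"` mode); the flag is Bernoulli at the
#' logistic psychometric probability.
#'
#' @param trial list with `condition`, `trajectory`, `windows`.
#' @param benefit_db numeric length-5 predicted benefit per word (dB).
#' @param u_j participant random intercept (logit units).
#' @param config a [cohort_config()].
#' @return logical length-5 word-correct flags; attribute `moving` records
#'   the per-word motion gate.
#' @export
gen_responses <- function(trial, benefit_db, u_j, config) {
  stopifnot(all(is.finite(benefit_db)))
  win <- trial$windows$words
  moving <- if (config$delta_mode == "trial_constant") {
    rep(trial$condition != "Static", 5)
  } else {
    vapply(seq_len(5), function(i)
      window_rms_speed(trial$trajectory, win$onset[i], win$offset[i]) >
        config$motion_threshold, logical(1))
  }
  eff <- benefit_db - config$delta * moving
  p <- plogis(config$beta0 + config$beta1 * eff + u_j)
  structure(as.logical(rbinom(5, 1, p)), moving = moving, p = p)
}

#' Generate a full synthetic cohort
#'
#' Composes the design, trajectories, word windows and responses for every
#' participant; fully reproducible from the config seed (the RNG seed is
#' set at entry).
#'
#' @param config a [cohort_config()].
#' @param benefit_maps named list of [benefit_map()]s keyed by target
#'   azimuth (`"0"`, `"-90"`, `"90"`, `"180"`). Required when moving
#'   conditions are generated; for Static-only cohorts it may be `NULL`
#'   (the head barely moves, so the orientation benefit is taken as 0).
#' @param conditions subset of conditions to generate (default all).
#' @return list of trial records; each has `participant`, `block`,
#'   `trial`, `condition`, `target`, `trajectory`, `windows`,
#'   `words_correct`, `predicted_db` (the per-word predictor used),
#'   `moving` (per-word motion gate). Attribute `u` stores the true
#'   participant intercepts.
#' @export
gen_cohort <- function(config, benefit_maps = NULL,
                       conditions = config$conditions) {
  set.seed(config$seed)
  if (any(conditions != "Static") && is.null(benefit_maps))
    stop("benefit_maps required to generate moving conditions")
  u <- rnorm(config$n_participants, 0, config$sigma_u)
  trials <- list()
  for (pt in seq_len(config$n_participants)) {
    des <- make_design(config)
    des <- des[des$condition %in% conditions, , drop = FALSE]
    for (i in seq_len(nrow(des))) {
      cond <- des$condition[i]; targ <- des$target[i]
      traj <- gen_trajectory(cond, targ, config, pt,
                             trial = (des$block[i] - 1) * 48 + des$trial[i])
      win <- gen_word_windows(config)
      ## predictor: spatial unmasking (dB re co-located) along the
      ## trajectory; without maps (Static-only cohorts) the frozen yaw-0
      ## model values stand in
      pred <- if (!is.null(benefit_maps)) {
        trajectory_benefit(benefit_maps[[as.character(targ)]], traj, win)
      } else {
        rep(config$static_predictions[[as.character(targ)]], 5)
      }
      rec <- list(participant = pt, block = des$block[i],
                  trial = traj$trial, condition = cond, target = targ,
                  trajectory = traj, windows = win)
      resp <- gen_responses(rec, pred, u[pt], config)
      rec$words_correct <- as.logical(resp)
      rec$moving <- attr(resp, "moving")
      rec$predicted_db <- pred
      trials[[length(trials) + 1]] <- rec
    }
  }
  attr(trials, "u") <- u
  attr(trials, "config") <- config
  trials
}

#' Export a cohort to plain-text files
#'
#' Writes the trajectory CSV, a trials TSV (participant, block, trial,
#' condition, target_deg, word1..word5 correctness) and a YAML config dump
#' recording the seed.
#'
#' @param trials a [gen_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(trials, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_trajectory_csv(trials, file.path(dir, "trajectories.csv"))
  tab <- do.call(rbind, lapply(trials, function(tr) {
    w <- as.integer(tr$words_correct)
    data.frame(participant = tr$participant, block = tr$block,
               trial = tr$trial, condition = tr$condition,
               target_deg = tr$target, word1 = w[1], word2 = w[2],
               word3 = w[3], word4 = w[4], word5 = w[5])
  }))
  write.table(tab, file.path(dir, "trials.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cfg <- attr(trials, "config")
  if (!is.null(cfg))
    yaml::write_yaml(unclass(cfg)[setdiff(names(cfg), "")],
                     file.path(dir, "config.yaml"))
  invisible(dir)
}

## Model-predicted static spatial unmasking (dB re the co-located frontal
## configuration) at yaw 0 in the default room, one value per target
## azimuth; computed once with benefit-map settings (0.3 s image limit,
## 44.1 kHz, 1 deg grid) and frozen here as the generator's psychometric
## predictors. The left/right asymmetry reflects the off-centre listener.
STATIC_PREDICTIONS <- c(`0` = 0, `-90` = 4.82, `90` = 4.87, `180` = 1.63)
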