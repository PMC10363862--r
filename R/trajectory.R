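## Head-yaw trajectories, preprocessing, and circular statistics.

#' Construct a head-yaw trajectory
#'
#' @param time numeric timestamps in seconds, uniformly spaced (default
#'   tracking rate 358.6 Hz), strictly increasing.
#' @param yaw numeric yaw in degrees, referenced to the interferer
#'   direction at trial start.
#' @param participant,trial optional identifiers.
#' @return object of class `trajectory`.
#' @export
trajectory <- function(time, yaw, participant = NA, trial = NA) {
  stopifnot(length(time) == length(yaw), length(time) >= 2)
  dt <- diff(time)
  if (any(dt <= 0)) stop("timestamps must be strictly increasing")
  if (diff(range(dt)) > 1e-6)
    stop("timestamps must be uniform within 1e-6 s")
  if (any(!is.finite(yaw))) stop("yaw must be finite")
  structure(list(time = time, yaw = yaw, rate = 1 / mean(dt),
                 participant = participant, trial = trial),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d samples @ %.1f Hz, yaw range [%.1f, %.1f] deg\n",
              length(x$time), x$rate, min(x$yaw), max(x$yaw)))
  invisible(x)
}

#' Word windows of a sentence
#'
#' Five non-overlapping (onset, offset) intervals covering the words of a
#' sentence, plus a post-final window of fixed duration used to summarise
#' the orientation reached after the sentence.
#'
#' @param onsets,offsets numeric length-5 vectors in seconds.
#' @param post_duration duration of the window following the final word
#'   offset (default 0.5 s).
#' @return object of class `word_windows` with elements `words`
#'   (data.frame onset/offset) and `post` (c(onset, offset)).
#' @export
word_windows <- function(onsets, offsets, post_duration = 0.5) {
  stopifnot(length(onsets) == 5, length(offsets) == 5)
  if (any(offsets <= onsets)) stop("offsets must exceed onsets")
  if (any(diff(as.numeric(rbind(onsets, offsets))) < -1e-12))
    stop("word windows must be increasing and non-overlapping")
  structure(list(words = data.frame(onset = onsets, offset = offsets),
                 post = c(offsets[5], offsets[5] + post_duration)),
            class = "word_windows")
}

#' Preprocess a raw yaw series
#'
#' Subtracts the reference orientation, unwraps (no jumps above 180 deg
#' between consecutive samples), and smooths with a normalised Kaiser
#' window of 27 ms, applied twice forward-backward so the net smoother has
#' zero phase.
#'
#' @param time numeric timestamps (s), uniform.
#' @param raw_yaw numeric raw yaw series (deg).
#' @param reference_yaw reference orientation (deg) subtracted before
#'   unwrapping (default 0).
#' @param window_s smoothing window length in seconds (default 0.027).
#' @param beta Kaiser shape parameter (default 5).
#' @param participant,trial forwarded to [trajectory()].
#' @return a smoothed [trajectory()].
#' @export
preprocess <- function(time, raw_yaw, reference_yaw = 0, window_s = 0.027,
                       beta = 5, participant = NA, trial = NA) {
  tr <- trajectory(time, rep(0, length(time)), participant, trial)
  y <- unwrap_deg(wrap_angle(raw_yaw - reference_yaw))
  m <- round(window_s * tr$rate)
  m <- max(3L, as.integer(m + (m %% 2 == 0)))     # odd, >= 3 taps
  w <- signal::kaiser(m, beta)
  w <- w / sum(w)
  y <- zero_phase_smooth(zero_phase_smooth(y, w), w)
  trajectory(time, y, participant, trial)
}

## Zero-phase FIR smoothing: symmetric kernel, forward-backward filtering
## with edge replication so constants pass through unchanged.
zero_phase_smooth <- function(x, w) {
  h <- (length(w) - 1) / 2
  pad <- c(rep(x[1], h), x, rep(x[length(x)], h))
  fwd <- stats::filter(pad, w, sides = 2)
  fwd <- as.numeric(fwd)[(h + 1):(h + length(x))]
  pad <- c(rep(fwd[1], h), fwd, rep(fwd[length(fwd)], h))
  bwd <- rev(as.numeric(stats::filter(rev(pad), w, sides = 2)))
  bwd[(h + 1):(h + length(x))]
}

#' Per-word median orientation
#'
#' @param traj a [trajectory()].
#' @param windows a [word_windows()] within the trajectory span.
#' @return numeric length-5, median yaw (deg) per word window.
#' @export
per_word_orientation <- function(traj, windows) {
  span <- range(traj$time)
  win <- windows$words
  if (any(win$onset < span[1] - 1e-9) || any(win$offset > span[2] + 1e-9))
    stop("word windows outside the trajectory time span")
  vapply(seq_len(nrow(win)), function(i) {
    sel <- traj$time >= win$onset[i] & traj$time < win$offset[i]
    if (!any(sel)) stop("empty word window ", i)
    median(traj$yaw[sel])
  }, numeric(1))
}

## ---- circular statistics ---------------------------------------------------

circ_dist <- function(a, b) {
  d <- abs(wrap_angle(a - b))
  d
}

#' Circular mean of angles in degrees
#'
#' @param angles numeric angles (deg).
#' @return mean direction in (-180, 180].
#' @export
circ_mean <- function(angles) {
  a <- deg2rad(angles)
  wrap_angle(rad2deg(atan2(mean(sin(a)), mean(cos(a)))))
}

#' Circular median of angles in degrees
#'
#' The minimiser of the mean absolute circular deviation, searched over
#' the sample angles. Ties are broken towards the circular mean; exactly
#' balanced ties return the circular mean of the tied minimisers (so
#' `{350, 10}` gives 0, not 180).
#'
#' @param angles numeric angles (deg), length >= 1.
#' @return circular median in (-180, 180].
#' @export
circ_median <- function(angles) {
  stopifnot(length(angles) >= 1)
  a <- wrap_angle(angles)
  cand <- unique(a)
  dev <- vapply(cand, function(m) mean(circ_dist(a, m)), numeric(1))
  mins <- cand[dev <= min(dev) + 1e-12]
  if (length(mins) == 1) return(mins)
  mu <- circ_mean(a)
  dmu <- circ_dist(mins, mu)
  near <- mins[dmu <= min(dmu) + 1e-12]
  if (length(near) == 1) return(near)
  circ_mean(near)
}

#' Circular normalized variance
#'
#' `1 - R` with `R` the mean resultant length; 0 for concentrated samples,
#' 1 when directions cancel completely.
#'
#' @param angles numeric angles (deg), length >= 1.
#' @return value in `[0, 1]`.
#' @export
circ_variance <- function(angles) {
  stopifnot(length(angles) >= 1)
  a <- deg2rad(angles)
  r <- sqrt(mean(cos(a))^2 + mean(sin(a))^2)
  1 - min(1, r)
}

## Kuiper V for a 0/1 label vector along the sorted pooled circle.
## lab: logical, TRUE for sample a, along sorted pooled angles.
kuiper_v_labels <- function(lab, n_a, n_b) {
  fa <- cumsum(lab) / n_a
  fb <- cumsum(!lab) / n_b
  d <- fa - fb
  max(d, 0) + max(-d, 0)
}

#' Two-sample Kuiper test for circular data
#'
#' Statistic `V = max(F_a - F_b) + max(F_b - F_a)` over the circle, which
#' is invariant to the choice of origin (unlike Kolmogorov-Smirnov). The
#' p-value is obtained by permutation of the pooled labels; set the RNG
#' seed for reproducibility.
#'
#' @param sample_a,sample_b numeric angle samples (deg), each of length
#'   >= 5.
#' @param n_permutations number of label permutations (default 2000; fewer
#'   than 100 triggers a warning).
#' @return list with `statistic` (V), `p_value`, `n_permutations`.
#' @export
kuiper_two_sample <- function(sample_a, sample_b, n_permutations = 2000) {
  stopifnot(length(sample_a) >= 5, length(sample_b) >= 5)
  if (n_permutations < 100)
    warning("fewer than 100 permutations: p-value resolution is poor")
  n_a <- length(sample_a); n_b <- length(sample_b)
  pooled <- wrap_angle(c(sample_a, sample_b))
  o <- order(pooled)
  lab <- c(rep(TRUE, n_a), rep(FALSE, n_b))[o]
  v_obs <- kuiper_v_labels(lab, n_a, n_b)
  n <- n_a + n_b
  v_perm <- vapply(seq_len(n_permutations), function(i) {
    kuiper_v_labels(sample(lab), n_a, n_b)
  }, numeric(1))
  p <- (1 + sum(v_perm >= v_obs - 1e-12)) / (n_permutations + 1)
  list(statistic = v_obs, p_value = p, n_permutations = n_permutations)
}

## ---- trajectory CSV I/O ----------------------------------------------------

#' Write trajectories to CSV
#'
#' Columns: `time_s`, `yaw_deg`, `participant`, `trial`, `condition`,
#' `target_deg` (UTF-8, header row).
#'
#' @param trials list of trial records (see [gen_cohort()]) or a single
#'   trajectory wrapped in a list with `condition`/`target` fields.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(trials, path) {
  dfs <- lapply(trials, function(tr)
    data.frame(time_s = tr$trajectory$time, yaw_deg = tr$trajectory$yaw,
               participant = tr$participant, trial = tr$trial,
               condition = tr$condition, target_deg = tr$target))
  write.csv(do.call(rbind, dfs), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trajectory CSV written by [write_trajectory_csv()]
#'
#' @param path CSV path.
#' @return data.frame with one row per sample.
#' @export
read_trajectory_csv <- function(path) {
  df <- read.csv(path)
  need <- c("time_s", "yaw_deg", "participant", "trial")
  if (!all(need %in% names(df)))
    stop("trajectory CSV must contain columns: ",
         paste(need, collapse = ", "))
  df
}
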