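## Scene and head-model containers for the shoebox room simulation.

#' Construct a shoebox room scene
#'
#' A scene is a rectangular (shoebox) room with frequency-dependent uniform
#' wall absorption, one listener, and one or more point sources placed
#' relative to the listener by azimuth and distance.
#'
#' Coordinate convention: right-handed room frame with z up. The listener
#' faces the +x axis at yaw 0; azimuths are degrees clockwise seen from above
#' (positive = to the listener's right), so a source at azimuth `a` and
#' distance `d` sits at `listener + d * (cos a, -sin a, 0)`.
#'
#' @param dims length-3 numeric, room dimensions (Lx, Ly, Lz) in meters.
#' @param band_absorption named numeric vector of wall absorption
#'   coefficients in (0, 1], names are octave-band centre frequencies in Hz.
#' @param listener_position length-3 numeric (x, y, z) in meters, strictly
#'   inside the room.
#' @param sources data.frame with columns `azimuth` (deg, listener-relative),
#'   `distance` (m, > 0) and `level` (dB SPL).
#' @param speed_of_sound speed of sound in m/s.
#' @return object of class `room_scene`.
#' @export
room_scene <- function(dims, band_absorption, listener_position, sources,
                       speed_of_sound = SPEED_OF_SOUND) {
  dims <- as.numeric(dims)
  stopifnot(length(dims) == 3, all(dims > 0))
  alpha <- as.numeric(band_absorption)
  bands <- as.numeric(names(band_absorption))
  if (any(is.na(bands)) || is.unsorted(bands, strictly = TRUE))
    stop("band_absorption must be named by strictly increasing frequencies (Hz)")
  if (any(alpha <= 0) || any(alpha > 1))
    stop("absorption coefficients must lie in (0, 1]")
  lp <- as.numeric(listener_position)
  stopifnot(length(lp) == 3)
  if (any(lp <= 0) || any(lp >= dims))
    stop("listener must be strictly inside the room")
  sources <- as.data.frame(sources)
  stopifnot(all(c("azimuth", "distance") %in% names(sources)))
  if (is.null(sources$level)) sources$level <- 0
  if (any(sources$distance <= 0)) stop("source distance must be > 0")
  sp <- source_positions(lp, sources$azimuth, sources$distance)
  inside <- sp > 0 & sp < matrix(dims, nrow(sp), 3, byrow = TRUE)
  if (!all(inside)) stop("all sources must be strictly inside the room")
  structure(
    list(dims = dims, band_freqs = bands, band_absorption = alpha,
         listener_position = lp, sources = sources,
         source_positions = sp, speed_of_sound = speed_of_sound),
    class = "room_scene")
}

source_positions <- function(listener, azimuth, distance) {
  a <- deg2rad(azimuth)
  cbind(listener[1] + distance * cos(a),
        listener[2] - distance * sin(a),
        listener[3])
}

#' @export
print.room_scene <- function(x, ...) {
  cat(sprintf("room_scene: %.1f x %.1f x %.1f m, %d source(s), %d bands\n",
              x$dims[1], x$dims[2], x$dims[3], nrow(x$sources),
              length(x$band_freqs)))
  invisible(x)
}

#' Construct a rigid-sphere head model
#'
#' Analytic binaural receiver: interaural time differences follow the
#' Woodworth ray-path construction on a rigid sphere and interaural level
#' differences use a first-order (one-pole/one-zero) head-shadow filter
#' evaluated at band centre frequencies.
#'
#' @param radius sphere radius in meters.
#' @param ear_azimuths length-2 numeric, (left, right) ear azimuths in the
#'   head frame in degrees; must be symmetric about the midline.
#' @param yaw head yaw in the room frame, degrees.
#' @return object of class `head_model`.
#' @export
head_model <- function(radius = 0.0875, ear_azimuths = c(-100, 100), yaw = 0) {
  stopifnot(radius > 0, length(ear_azimuths) == 2)
  if (abs(ear_azimuths[1] + ear_azimuths[2]) > 1e-9)
    stop("ear azimuths must be symmetric about the midline")
  structure(list(radius = radius, ear_azimuths = ear_azimuths, yaw = yaw),
            class = "head_model")
}

#' Invert Eyring's reverberation formula for a uniform absorption coefficient
#'
#' Solves Eyring's formula `T = (24 ln 10 / c) * V / (-S * ln(1 - alpha))`
#' for `alpha` given a shoebox geometry and a target T30.
#'
#' @param dims length-3 room dimensions in meters.
#' @param target_t30 target reverberation time in seconds (> 0).
#' @param speed_of_sound speed of sound in m/s.
#' @return absorption coefficient in (0, 1).
#' @export
eyring_alpha <- function(dims, target_t30, speed_of_sound = SPEED_OF_SOUND) {
  stopifnot(length(dims) == 3, all(dims > 0), target_t30 > 0)
  V <- prod(dims)
  S <- 2 * (dims[1] * dims[2] + dims[1] * dims[3] + dims[2] * dims[3])
  k <- 24 * log(10) * V / (speed_of_sound * S * target_t30)
  alpha <- 1 - exp(-k)
  if (alpha >= 1 - 1e-12)
    stop("target T30 too short: required absorption >= 1")
  alpha
}

#' Eyring's forward reverberation-time prediction
#'
#' @inheritParams eyring_alpha
#' @param alpha uniform wall absorption coefficient in (0, 1).
#' @return predicted T30 in seconds.
#' @export
eyring_t30 <- function(dims, alpha, speed_of_sound = SPEED_OF_SOUND) {
  stopifnot(alpha > 0, alpha < 1)
  V <- prod(dims)
  S <- 2 * (dims[1] * dims[2] + dims[1] * dims[3] + dims[2] * dims[3])
  24 * log(10) * V / (speed_of_sound * S * (-log(1 - alpha)))
}

#' Band absorptions from measured reverberation times
#'
#' Inverts a reverberation formula per octave band: either the specular
#' image-source decay law ([calibrate_alpha()], default -- the simulated
#' impulse response then reproduces the target T30s) or Eyring's
#' diffuse-field formula ([eyring_alpha()]). The 125 Hz band copies the
#' 250 Hz value and the 8 kHz band copies 4 kHz, extending the measured
#' 250 Hz - 4 kHz range to cover the auditory analysis bands.
#'
#' @param dims room dimensions (m).
#' @param t30_by_band named numeric vector, T30 (s) per octave-band centre
#'   frequency (Hz).
#' @param extend extend with 125 Hz and 8 kHz edge bands (default TRUE).
#' @param method `"ism"` (specular decay law) or `"eyring"`.
#' @return named absorption vector usable as `band_absorption`.
#' @export
absorption_from_t30 <- function(dims, t30_by_band, extend = TRUE,
                                method = c("ism", "eyring")) {
  method <- match.arg(method)
  invert <- if (method == "ism") calibrate_alpha else eyring_alpha
  alpha <- vapply(t30_by_band, function(t) invert(dims, t), numeric(1))
  names(alpha) <- names(t30_by_band)
  if (extend) {
    f <- as.numeric(names(alpha))
    lo <- alpha[which.min(f)]
    hi <- alpha[which.max(f)]
    out <- c(structure(lo, names = as.character(min(f) / 2)), alpha,
             structure(hi, names = as.character(max(f) * 2)))
    alpha <- out
  }
  alpha
}

## Octave-band T30s of the simulated room used throughout as the default
## scene (seconds, Schroeder -5..-35 dB fit).
DEFAULT_T30 <- c(`250` = 1.16, `500` = 1.34, `1000` = 1.15,
                 `2000` = 1.02, `4000` = 0.85)

## Calibrated band absorptions of the default room, memoised per session
## (the calibration root-find costs a couple of seconds).
.room_cache <- new.env(parent = emptyenv())
default_absorption <- function() {
  if (is.null(.room_cache$alpha))
    .room_cache$alpha <- absorption_from_t30(c(11, 13, 3), DEFAULT_T30)
  .room_cache$alpha
}

#' Default reverberant scene
#'
#' The 11 x 13 x 3 m mildly reverberant room used by the self-rotation
#' speech test: listener off-centre at (4, 7, 1.8) m, speech-shaped noise
#' interferer at azimuth 0 deg and a speech target at a configurable
#' azimuth, both at 2.1 m. Band absorptions are calibrated so the
#' simulated specular decay reproduces the room's octave-band T30s
#' (1.16/1.34/1.15/1.02/0.85 s at 250 Hz ... 4 kHz); see
#' [calibrate_alpha()].
#'
#' @param target_azimuth target azimuth in degrees (0, +/-90 or 180 in the
#'   experiment; any value accepted).
#' @param target_level,interferer_level presentation levels in dB SPL.
#' @param anechoic if TRUE, all absorptions are set to 1 (free field).
#' @return `room_scene` whose source 1 is the target and source 2 the
#'   interferer.
#' @export
default_scene <- function(target_azimuth = 90, target_level = 60,
                          interferer_level = 70, anechoic = FALSE) {
  dims <- c(11, 13, 3)
  alpha <- default_absorption()
  if (anechoic) alpha[] <- 1
  room_scene(
    dims = dims,
    band_absorption = alpha,
    listener_position = c(4, 7, 1.8),
    sources = data.frame(
      azimuth = c(target_azimuth, 0),
      distance = c(2.1, 2.1),
      level = c(target_level, interferer_level),
      role = c("target", "interferer")))
}

#' Read a scene from a YAML or JSON configuration file
#'
#' Expected keys: `dims` (3 numbers, m), `absorption` (map band Hz -> alpha),
#' `listener` (3 numbers, m), `sources` (list of maps with `azimuth` deg,
#' `distance` m, optional `level` dB SPL), optional `speed_of_sound`.
#'
#' @param path file path; `.json` is parsed as JSON, anything else as YAML.
#' @return `room_scene`.
#' @export
read_scene <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  ab <- unlist(cfg$absorption)
  src <- if (is.data.frame(cfg$sources)) {
    cfg$sources
  } else {
    do.call(rbind, lapply(cfg$sources, function(s)
      data.frame(azimuth = s$azimuth, distance = s$distance,
                 level = s$level %||% 0)))
  }
  room_scene(dims = unlist(cfg$dims), band_absorption = ab,
             listener_position = unlist(cfg$listener), sources = src,
             speed_of_sound = cfg$speed_of_sound %||% SPEED_OF_SOUND)
}
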