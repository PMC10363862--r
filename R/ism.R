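## Shoebox image-source enumeration and binaural rendering.
##
## Images follow the classic mirror construction: along each axis the image
## coordinate is (1-2u) p + 2 n L with parity bit u in {0,1} and integer
## shift n; the number of wall hits on that axis is |n - u| + |n|. With a
## uniform per-band absorption alpha the pressure reflection coefficient is
## r = sqrt(1 - alpha) per hit, so an image reflected N times carries a
## band attenuation r^N.

#' Enumerate image sources within a travel-time limit
#'
#' @param scene a [room_scene()].
#' @param source_index which source of the scene to mirror (default 1).
#' @param time_limit maximum propagation time in seconds; only images whose
#'   path length to the listener is at most `speed_of_sound * time_limit`
#'   are kept.
#' @return object of class `image_set`: positions, path lengths (to the
#'   listener), per-image reflection counts and the band absorption table
#'   needed to materialise per-band attenuations. Images with identically
#'   zero attenuation in every band (fully absorbed, e.g. the anechoic
#'   case) are dropped; the direct-path image always survives. Images are
#'   ordered by path length, direct path first.
#' @export
enumerate_images <- function(scene, source_index = 1, time_limit = 0.3) {
  stopifnot(inherits(scene, "room_scene"), time_limit > 0)
  p <- scene$source_positions[source_index, ]
  L <- scene$listener_position
  dims <- scene$dims
  dmax <- scene$speed_of_sound * time_limit

  axis_tab <- function(ax) {
    nmax <- ceiling((dmax + dims[ax]) / (2 * dims[ax])) + 1L
    n <- seq.int(-nmax, nmax)
    out <- list()
    for (u in 0:1) {
      coord <- (1 - 2 * u) * p[ax] + 2 * n * dims[ax]
      keep <- abs(coord - L[ax]) <= dmax
      out[[u + 1L]] <- list(coord = coord[keep],
                            hits = abs(n[keep] - u) + abs(n[keep]))
    }
    list(coord = c(out[[1]]$coord, out[[2]]$coord),
         hits = c(out[[1]]$hits, out[[2]]$hits))
  }
  tx <- axis_tab(1); ty <- axis_tab(2); tz <- axis_tab(3)

  idx <- expand.grid(i = seq_along(tx$coord), j = seq_along(ty$coord),
                     k = seq_along(tz$coord), KEEP.OUT.ATTRS = FALSE)
  pos <- cbind(tx$coord[idx$i], ty$coord[idx$j], tz$coord[idx$k])
  d2 <- (pos[, 1] - L[1])^2 + (pos[, 2] - L[2])^2 + (pos[, 3] - L[3])^2
  keep <- d2 <= dmax^2
  pos <- pos[keep, , drop = FALSE]
  nref <- tx$hits[idx$i][keep] + ty$hits[idx$j][keep] + tz$hits[idx$k][keep]
  dist <- sqrt(d2[keep])

  ## drop fully absorbed images (zero attenuation in every band)
  rmax <- sqrt(1 - min(scene$band_absorption))
  alive <- nref == 0L | rmax > 0
  pos <- pos[alive, , drop = FALSE]
  nref <- nref[alive]
  dist <- dist[alive]

  o <- order(dist, nref)
  structure(
    list(positions = pos[o, , drop = FALSE], dist = dist[o],
         n_refl = nref[o], band_freqs = scene$band_freqs,
         band_absorption = scene$band_absorption,
         listener_position = L, speed_of_sound = scene$speed_of_sound,
         source_index = source_index),
    class = "image_set")
}

#' @export
print.image_set <- function(x, ...) {
  cat(sprintf("image_set: %d images, max path %.1f m, %d bands\n",
              length(x$dist), max(x$dist), length(x$band_freqs)))
  invisible(x)
}

#' Per-band pressure attenuation of each image
#'
#' @param images an `image_set`.
#' @return matrix (n images x n bands) of reflection-attenuation products
#'   `r_b^N` with `r_b = sqrt(1 - alpha_b)`; 1 in every band for the direct
#'   path.
#' @export
image_attenuation <- function(images) {
  r <- sqrt(1 - images$band_absorption)
  out <- outer(images$n_refl, r, function(n, rb) rb^n)
  colnames(out) <- as.character(images$band_freqs)
  out
}

## ---- rigid-sphere receiver -------------------------------------------------

## Angle (deg, 0..180) between each image direction and an ear direction.
## dirs: unit vectors (n x 3) from listener to images; ear azimuth in room
## frame (head yaw already applied), horizontal.
incidence_angle <- function(dirs, ear_az_room) {
  a <- deg2rad(ear_az_room)
  ear <- c(cos(a), -sin(a), 0)
  cs <- pmin(1, pmax(-1, dirs %*% ear))
  rad2deg(acos(drop(cs)))
}

## Woodworth per-ear propagation delay correction (s) relative to the head
## centre, for incidence angle gamma (deg) from the ear axis.
sphere_ear_delay <- function(gamma_deg, radius, c0) {
  g <- deg2rad(gamma_deg)
  ifelse(g <= pi / 2, -radius / c0 * cos(g), radius / c0 * (g - pi / 2))
}

## First-order head-shadow magnitude (one-pole/one-zero sphere filter) at
## frequency f (Hz) and incidence angle gamma (deg) from the ear axis.
sphere_shadow_gain <- function(gamma_deg, f, radius, c0,
                               alpha_min = 0.1, theta_min = 150) {
  al <- (1 + alpha_min / 2) + (1 - alpha_min / 2) *
    cos(deg2rad(gamma_deg) * 180 / theta_min)
  x <- pi * f * radius / c0
  sqrt((1 + (al * x)^2) / (1 + x^2))
}

## ---- band impulse trains and spectra --------------------------------------

## Nearest power of two >= n (for FFT work).
next_pow2 <- function(n) 2^ceiling(log2(n))

## Accumulate impulse amplitudes into a train of length n at (possibly
## fractional) sample positions t (in samples, 0-based).
accumulate_train <- function(t, amp, n, fractional = FALSE) {
  tr <- numeric(n)
  if (!fractional) {
    i <- round(t) + 1
    keep <- i >= 1 & i <= n
    s <- rowsum(amp[keep], i[keep])
    tr[as.integer(rownames(s))] <- s
  } else {
    i0 <- floor(t) + 1
    w <- t - floor(t)
    for (off in 0:1) {
      ii <- i0 + off
      ww <- if (off == 0) 1 - w else w
      keep <- ii >= 1 & ii <= n
      if (any(keep)) {
        s <- rowsum(amp[keep] * ww[keep], ii[keep])
        tr[as.integer(rownames(s))] <- tr[as.integer(rownames(s))] + s
      }
    }
  }
  tr
}

## Triangular log-frequency interpolation weights across octave bands.
## freqs: physical frequency of each FFT bin (Hz, >= 0); bands: centres.
## Rows sum to 1; constant extrapolation outside the band range.
spectral_band_weights <- function(freqs, bands) {
  B <- length(bands)
  lf <- log2(pmax(freqs, 1e-6))
  lb <- log2(bands)
  W <- matrix(0, length(freqs), B)
  W[freqs <= bands[1], 1] <- 1
  W[freqs >= bands[B], B] <- 1
  for (b in seq_len(B - 1)) {
    in_seg <- freqs > bands[b] & freqs < bands[b + 1]
    if (any(in_seg)) {
      w_hi <- (lf[in_seg] - lb[b]) / (lb[b + 1] - lb[b])
      W[in_seg, b] <- 1 - w_hi
      W[in_seg, b + 1] <- w_hi
    }
  }
  W
}

## Physical frequency (Hz) of FFT bins 1..nfft (two-sided).
fft_bin_freqs <- function(nfft, fs) {
  k <- 0:(nfft - 1)
  f <- k * fs / nfft
  pmin(f, fs - f)
}

## Core renderer: band impulse trains for one receiver channel.
## gains: n_images x n_bands amplitude matrix (already includes 1/d and any
## receiver gain); delays: per-image delay in seconds. All bands share the
## image delays, so the scatter-add is a single matrix rowsum.
band_trains <- function(delays, gains, fs, n) {
  i <- round(delays * fs) + 1
  keep <- i >= 1 & i <= n
  s <- rowsum(gains[keep, , drop = FALSE], i[keep])
  out <- matrix(0, n, ncol(gains))
  out[as.integer(rownames(s)), ] <- s
  out
}

## Sum band trains into one broadband spectrum (length nfft, complex).
trains_to_spectrum <- function(trains, band_freqs, fs, nfft) {
  W <- spectral_band_weights(fft_bin_freqs(nfft, fs), band_freqs)
  X <- complex(length.out = nfft)
  for (b in seq_len(ncol(trains))) {
    if (any(trains[, b] != 0))
      X <- X + fft(c(trains[, b], numeric(nfft - nrow(trains)))) * W[, b]
  }
  X
}

## Internal: per-ear delays (s) and band gain matrices for a yaw.
ear_geometry <- function(images, head, yaw) {
  L <- images$listener_position
  rel <- sweep(images$positions, 2, L)
  dirs <- rel / images$dist
  c0 <- images$speed_of_sound
  lapply(c(left = 1, right = 2), function(e) {
    gamma <- incidence_angle(dirs, yaw + head$ear_azimuths[e])
    gains <- matrix(sapply(images$band_freqs, function(f)
      sphere_shadow_gain(gamma, f, head$radius, c0)),
      nrow = length(images$dist))
    list(delay = images$dist / c0 +
           sphere_ear_delay(gamma, head$radius, c0),
         gains = gains)
  })
}

#' Render a binaural room impulse response from an image set
#'
#' Each image contributes, at each ear, an impulse at delay
#' `(path length)/c` plus the rigid-sphere ear delay, with amplitude
#' `(1/path) * band attenuation * head-shadow gain`. Band-limited wall and
#' head filtering is applied spectrally: per-octave-band impulse trains are
#' combined with triangular log-frequency weights and inverse-transformed
#' to a broadband pair.
#'
#' @param images an [enumerate_images()] result (non-empty).
#' @param head a [head_model()]; its `yaw` orients the receiver.
#' @param sample_rate sampling rate in Hz (>= 16000).
#' @param duration impulse-response length in seconds; defaults to the
#'   maximum path delay plus 5 ms.
#' @param fractional_delay "nearest" (default) rounds impulse positions to
#'   the nearest sample; "linear" splits them across adjacent samples.
#' @return object of class `brir`: `left`, `right` (numeric, equal length),
#'   `sample_rate`, `duration`.
#' @export
render_brir <- function(images, head, sample_rate = 44100, duration = NULL,
                        fractional_delay = c("nearest", "linear")) {
  stopifnot(inherits(images, "image_set"))
  if (length(images$dist) == 0) stop("empty image set")
  if (sample_rate < 16000) stop("sample_rate must be >= 16 kHz")
  fractional_delay <- match.arg(fractional_delay)
  att <- image_attenuation(images)
  geo <- ear_geometry(images, head, head$yaw)
  max_delay <- max(images$dist) / images$speed_of_sound +
    head$radius / images$speed_of_sound
  if (is.null(duration)) duration <- max_delay + 0.005
  if (duration < max_delay) stop("duration shorter than the longest path")
  n <- ceiling(duration * sample_rate)
  nfft <- next_pow2(n)
  chans <- lapply(geo, function(g) {
    gains <- att * g$gains / images$dist
    tr <- if (fractional_delay == "nearest") {
      band_trains(g$delay, gains, sample_rate, n)
    } else {
      B <- ncol(gains)
      out <- matrix(0, n, B)
      t <- g$delay * sample_rate
      for (b in seq_len(B))
        out[, b] <- accumulate_train(t, gains[, b], n, fractional = TRUE)
      out
    }
    X <- trains_to_spectrum(tr, images$band_freqs, sample_rate, nfft)
    Re(fft(X, inverse = TRUE))[seq_len(n)] / nfft
  })
  structure(list(left = chans$left, right = chans$right,
                 sample_rate = sample_rate, duration = n / sample_rate),
            class = "brir")
}

#' Render a monaural (omnidirectional) room impulse response
#'
#' As [render_brir()] but with an ideal point receiver at the listener
#' position: no head shadow, no interaural delays.
#'
#' @inheritParams render_brir
#' @return numeric impulse response with attributes `sample_rate`.
#' @export
render_rir <- function(images, sample_rate = 44100, duration = NULL) {
  stopifnot(inherits(images, "image_set"))
  if (length(images$dist) == 0) stop("empty image set")
  att <- image_attenuation(images)
  delays <- images$dist / images$speed_of_sound
  if (is.null(duration)) duration <- max(delays) + 0.005
  n <- ceiling(duration * sample_rate)
  nfft <- next_pow2(n)
  tr <- band_trains(delays, att / images$dist, sample_rate, n)
  X <- trains_to_spectrum(tr, images$band_freqs, sample_rate, nfft)
  ir <- Re(fft(X, inverse = TRUE))[seq_len(n)] / nfft
  attr(ir, "sample_rate") <- sample_rate
  ir
}

#' @export
print.brir <- function(x, ...) {
  cat(sprintf("brir: %d samples @ %d Hz (%.3f s)\n",
              length(x$left), x$sample_rate, x$duration))
  invisible(x)
}
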