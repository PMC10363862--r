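## Binaural speech-intelligibility model: better-ear listening plus
## binaural unmasking (equalisation-cancellation style BMLD), evaluated per
## gammatone band and combined with speech-importance weights. Applied to
## binaural room impulse responses; no temporal dynamics (a "static" model).

## ---- auditory scales -------------------------------------------------------

erb_scale <- function(f) 21.4 * log10(4.37e-3 * f + 1)
erb_scale_inv <- function(e) (10^(e / 21.4) - 1) / 4.37e-3
erb_bandwidth <- function(f) 24.7 * (4.37e-3 * f + 1)

## ANSI S3.5-1997 one-third-octave band importance function for average
## speech (18 bands, 160 Hz - 8 kHz); sums to 1.
SII_THIRD_OCTAVE <- data.frame(
  f = c(160, 200, 250, 315, 400, 500, 630, 800, 1000, 1250, 1600, 2000,
        2500, 3150, 4000, 5000, 6300, 8000),
  w = c(0.0083, 0.0095, 0.0150, 0.0289, 0.0440, 0.0578, 0.0653, 0.0711,
        0.0818, 0.0844, 0.0882, 0.0898, 0.0868, 0.0844, 0.0771, 0.0527,
        0.0364, 0.0185))

#' Constants of the binaural intelligibility model
#'
#' Internal-noise parameters of the equalisation-cancellation stage
#' (amplitude jitter `sigma_eps`, time jitter `sigma_delta`), the gammatone
#' analysis bands, and the band importance weights.
#'
#' @param sigma_eps dimensionless internal amplitude jitter (default 0.25).
#' @param sigma_delta internal time jitter in seconds (default 105e-6).
#' @param n_bands number of ERB-spaced gammatone bands (default 16).
#' @param f_range frequency range of band centres in Hz.
#' @param weights `"sii"` (default) interpolates the one-third-octave
#'   speech-importance function to the band centres and renormalises;
#'   `"uniform"` weights all bands equally.
#' @return object of class `model_constants` with fields `sigma_eps`,
#'   `sigma_delta`, `band_centers`, `band_weights`.
#' @export
model_constants <- function(sigma_eps = 0.25, sigma_delta = 105e-6,
                            n_bands = 16, f_range = c(100, 8000),
                            weights = c("sii", "uniform")) {
  weights <- match.arg(weights)
  e <- seq(erb_scale(f_range[1]), erb_scale(f_range[2]), length.out = n_bands)
  fc <- erb_scale_inv(e)
  w <- if (weights == "uniform") {
    rep(1 / n_bands, n_bands)
  } else {
    wi <- approx(log(SII_THIRD_OCTAVE$f), SII_THIRD_OCTAVE$w, xout = log(fc),
                 rule = 2)$y
    wi / sum(wi)
  }
  structure(list(sigma_eps = sigma_eps, sigma_delta = sigma_delta,
                 band_centers = fc, band_weights = w),
            class = "model_constants")
}

## 4th-order gammatone power response |G(f)|^2, normalised to 1 at fc,
## evaluated at physical frequencies f (Hz).
gammatone_power <- function(f, fc) {
  b <- 1.019 * erb_bandwidth(fc)
  (1 + ((f - fc) / b)^2)^(-4)
}

## Precomputed filterbank power responses over the FFT bins (nfft x nb).
gammatone_bank <- function(nfft, fs, fc) {
  f <- fft_bin_freqs(nfft, fs)
  vapply(fc, function(x) gammatone_power(f, x), numeric(nfft))
}

## ---- band decomposition ----------------------------------------------------

## Sub-sample cross-correlation peak: discrete argmax plus three-point
## parabolic refinement (removes the sample-grid quantisation of the lag,
## and keeps mirrored scenes exactly mirror-symmetric).
xcorr_peak <- function(c_vals, lag_s) {
  i <- which.max(c_vals)
  n <- length(c_vals)
  if (i == 1 || i == n) return(list(lag = lag_s[i], val = c_vals[i]))
  y1 <- c_vals[i - 1]; y2 <- c_vals[i]; y3 <- c_vals[i + 1]
  den <- y1 - 2 * y2 + y3
  if (abs(den) < .Machine$double.eps * max(abs(c(y1, y2, y3)), 1))
    return(list(lag = lag_s[i], val = y2))
  d <- 0.5 * (y1 - y3) / den
  d <- max(-0.5, min(0.5, d))
  list(lag = lag_s[i] + d * (lag_s[2] - lag_s[1]),
       val = y2 - 0.25 * (y1 - y3) * d)
}

## Core: per-band ear energies, interaural coherence and phases from
## two-channel spectra (length nfft, two-sided).
band_parameters_spec <- function(XtL, XtR, XiL, XiR, fs, nfft, constants,
                                 max_lag = 1e-3, G2 = NULL) {
  fc <- constants$band_centers
  nb <- length(fc)
  if (is.null(G2)) G2 <- gammatone_bank(nfft, fs, fc)
  lag_n <- floor(max_lag * fs)
  ## lag ordering of ifft output: index 1 = lag 0, index nfft+1-m = -m;
  ## assemble indices so lags run ascending -max_lag .. +max_lag
  pos <- seq_len(lag_n + 1)
  neg <- nfft - lag_n + seq_len(lag_n)
  lag_idx <- c(neg, pos)
  lag_s <- c(-rev(seq_len(lag_n)), 0:lag_n) / fs

  PtL <- Mod(XtL)^2; PtR <- Mod(XtR)^2
  PiL <- Mod(XiL)^2; PiR <- Mod(XiR)^2
  CSt <- XtL * Conj(XtR)
  CSi <- XiL * Conj(XiR)

  out <- data.frame(band = fc, target_left = NA_real_, target_right = NA_real_,
                    interferer_left = NA_real_, interferer_right = NA_real_,
                    phase_target = NA_real_, phase_interferer = NA_real_,
                    coherence = NA_real_, degenerate = FALSE)
  for (b in seq_len(nb)) {
    g2 <- G2[, b]
    etl <- sum(PtL * g2) / nfft; etr <- sum(PtR * g2) / nfft
    eil <- sum(PiL * g2) / nfft; eir <- sum(PiR * g2) / nfft
    out$target_left[b] <- etl; out$target_right[b] <- etr
    out$interferer_left[b] <- eil; out$interferer_right[b] <- eir
    if (eil <= 0 || eir <= 0 || etl <= 0 || etr <= 0) {
      out$degenerate[b] <- TRUE
      next
    }
    ct <- Re(fft(CSt * g2, inverse = TRUE))[lag_idx] / nfft
    ci <- Re(fft(CSi * g2, inverse = TRUE))[lag_idx] / nfft
    pt <- xcorr_peak(ct, lag_s)
    pi_ <- xcorr_peak(ci, lag_s)
    out$phase_target[b] <- 2 * pi * fc[b] * pt$lag
    out$phase_interferer[b] <- 2 * pi * fc[b] * pi_$lag
    out$coherence[b] <- max(0, min(1, pi_$val / sqrt(eil * eir)))
  }
  class(out) <- c("band_decomposition", "data.frame")
  out
}

#' Per-band binaural parameters of a target/interferer BRIR pair
#'
#' For each gammatone band: the band-filtered impulse-response energy at
#' each ear, the interaural phases of target and interferer (from the lag
#' maximising the normalised interaural cross-correlation within +/- 1 ms,
#' refined to sub-sample precision by parabolic interpolation; the sign
#' convention makes a leading left channel give a negative lag and phase),
#' and the interaural coherence of the interferer (the maximum of that
#' normalised cross-correlation). Bands in which either signal has no
#' energy are flagged degenerate and excluded from the weighted sum
#' downstream.
#'
#' @param brir_target,brir_interferer `brir` objects with equal sample
#'   rates.
#' @param constants a [model_constants()].
#' @param max_lag cross-correlation search range in seconds.
#' @return `band_decomposition` data.frame, one row per band.
#' @export
band_parameters <- function(brir_target, brir_interferer,
                            constants = model_constants(), max_lag = 1e-3) {
  if (brir_target$sample_rate != brir_interferer$sample_rate)
    stop("BRIRs must share a sample rate")
  fs <- brir_target$sample_rate
  n <- max(length(brir_target$left), length(brir_interferer$left))
  ## headroom for linear (non-circular) cross-correlation at +/- max_lag
  nfft <- next_pow2(n + ceiling(max_lag * fs) + 1)
  pad <- function(x) c(x, numeric(nfft - length(x)))
  band_parameters_spec(fft(pad(brir_target$left)), fft(pad(brir_target$right)),
                       fft(pad(brir_interferer$left)),
                       fft(pad(brir_interferer$right)),
                       fs, nfft, constants, max_lag)
}

#' Binaural masking level difference of one band
#'
#' Equalisation-cancellation expression
#' `max(0, 10 log10((k - cos(phase_t - phase_i)) / (k - coherence_i)))`
#' with `k = (1 + sigma_eps^2) * exp((2 pi f_c)^2 * sigma_delta^2)`; the
#' internal jitter makes `k > 1`, so the advantage vanishes for
#' high-frequency bands and is floored at 0 dB.
#'
#' @param phase_t,phase_i interaural phases of target and interferer (rad).
#' @param coherence_i interferer interaural coherence in `[0, 1]`.
#' @param f_c band centre frequency in Hz.
#' @param constants a [model_constants()].
#' @return BMLD in dB (vectorised over the inputs).
#' @export
bmld <- function(phase_t, phase_i, coherence_i, f_c,
                 constants = model_constants()) {
  if (any(coherence_i < 0 | coherence_i > 1))
    stop("coherence must lie in [0, 1]")
  k <- (1 + constants$sigma_eps^2) *
    exp((2 * pi * f_c)^2 * constants$sigma_delta^2)
  if (any(k <= coherence_i))
    stop("internal-noise constant k <= coherence: invalid constants")
  pmax(0, 10 * log10((k - cos(phase_t - phase_i)) / (k - coherence_i)))
}

#' Effective target-to-interferer ratio of a band decomposition
#'
#' Per band, the better-ear ratio (the larger of the two ears'
#' target/interferer energy ratios, in dB) plus the band [bmld()]; the
#' band advantages are combined as an importance-weighted sum, with
#' weights renormalised over the non-degenerate bands.
#'
#' @param bd a [band_parameters()] result.
#' @param constants a [model_constants()].
#' @return effective TIR in dB.
#' @export
effective_tir <- function(bd, constants = model_constants()) {
  ok <- !bd$degenerate
  if (!any(ok)) stop("all bands degenerate: no usable energy")
  w <- constants$band_weights[ok] / sum(constants$band_weights[ok])
  be <- 10 * log10(pmax(bd$target_left[ok] / bd$interferer_left[ok],
                        bd$target_right[ok] / bd$interferer_right[ok]))
  bm <- bmld(bd$phase_target[ok], bd$phase_interferer[ok], bd$coherence[ok],
             bd$band[ok], constants)
  sum(w * (be + bm))
}

## ---- benefit maps ----------------------------------------------------------

## Channel spectra of one source for one yaw, from a precomputed geometry
## cache (images, attenuations, spectral weights).
yaw_spectra <- function(cache, head, yaw, fs, n, nfft) {
  geo <- ear_geometry(cache$images, head, yaw)
  lapply(geo, function(g) {
    gains <- cache$att * g$gains / cache$images$dist
    tr <- band_trains(g$delay, gains, fs, n)
    X <- complex(length.out = nfft)
    for (b in seq_len(ncol(tr))) {
      if (any(tr[, b] != 0))
        X <- X + fft(c(tr[, b], numeric(nfft - n))) * cache$W[, b]
    }
    X
  })
}

#' Head-orientation benefit map
#'
#' Evaluates the effective target-to-interferer ratio of the binaural
#' intelligibility model on a grid of head yaws covering the full circle.
#' The benefit scale is referenced to the co-located configuration
#' (target and interferer at the same position), whose effective TIR is
#' exactly 0 dB; a map value is therefore the spatial unmasking available
#' at that head orientation, and the co-located (frontal-target) map is
#' flat at ~0 dB. Yaw 0 faces the interferer, as at trial start.
#'
#' @param scene a [room_scene()] containing (at least) a target and an
#'   interferer source.
#' @param target_index,interferer_index source rows of the scene; a
#'   co-located pair is allowed and produces a flat map (with a message).
#' @param head a [head_model()].
#' @param grid_step yaw grid step in degrees (default 1).
#' @param time_limit image-source travel-time limit in seconds
#'   (default 0.3 s; raise for T30 work, lower for quick maps).
#' @param sample_rate rendering rate in Hz.
#' @param constants a [model_constants()].
#' @return object of class `benefit_map`: data.frame with `yaw` (deg) and
#'   `benefit` (dB); attributes carry the scene geometry and grid step.
#' @export
benefit_map <- function(scene, target_index = 1, interferer_index = 2,
                        head = head_model(), grid_step = 1,
                        time_limit = 0.3, sample_rate = 44100,
                        constants = model_constants()) {
  stopifnot(inherits(scene, "room_scene"))
  if (target_index == interferer_index)
    stop("target and interferer must be different source entries")
  if (isTRUE(all.equal(scene$sources$azimuth[target_index],
                       scene$sources$azimuth[interferer_index])))
    message("target and interferer are co-located; expect a flat map")
  fs <- sample_rate
  n <- ceiling(time_limit * fs)
  nfft <- next_pow2(n + ceiling(1e-3 * fs) + 1)
  W <- spectral_band_weights(fft_bin_freqs(nfft, fs), scene$band_freqs)
  mk_cache <- function(i) {
    im <- enumerate_images(scene, i, time_limit)
    list(images = im, att = image_attenuation(im), W = W)
  }
  ct <- mk_cache(target_index)
  ci <- mk_cache(interferer_index)
  G2 <- gammatone_bank(nfft, fs, constants$band_centers)
  yaws <- seq(0, 360 - grid_step, by = grid_step)
  tir <- vapply(yaws, function(y) {
    st <- yaw_spectra(ct, head, y, fs, n, nfft)
    si <- yaw_spectra(ci, head, y, fs, n, nfft)
    bd <- band_parameters_spec(st$left, st$right, si$left, si$right,
                               fs, nfft, constants, G2 = G2)
    effective_tir(bd, constants)
  }, numeric(1))
  structure(data.frame(yaw = yaws, benefit = tir),
            class = c("benefit_map", "data.frame"),
            reference = "co-located", grid_step = grid_step,
            target_azimuth = scene$sources$azimuth[target_index],
            interferer_azimuth = scene$sources$azimuth[interferer_index])
}

#' Look up map benefit at arbitrary yaws (nearest grid point)
#'
#' @param map a [benefit_map()].
#' @param yaw numeric yaw(s) in degrees (any winding).
#' @return benefit in dB at the nearest grid yaw(s).
#' @export
map_benefit <- function(map, yaw) {
  step <- attr(map, "grid_step")
  idx <- (round(yaw / step) * step) %% 360
  map$benefit[match(idx, map$yaw)]
}

#' Acoustically optimal orientation region
#'
#' All yaws whose benefit is within `margin` dB of the map maximum.
#'
#' @param map a [benefit_map()].
#' @param margin margin below the peak in dB (default 1).
#' @return object of class `optimal_region`: integer-degree yaws in the
#'   region, with attributes `peak` (dB) and `peak_yaw` (deg).
#' @export
optimal_region <- function(map, margin = 1) {
  pk <- max(map$benefit)
  yaws <- map$yaw[map$benefit >= pk - margin]
  structure(yaws, class = "optimal_region", margin = margin,
            peak = pk, peak_yaw = map$yaw[which.max(map$benefit)])
}

#' @export
print.optimal_region <- function(x, ...) {
  cat(sprintf("optimal_region: %d yaw(s) within %.2f dB of peak %.2f dB at %g deg\n",
              length(x), attr(x, "margin"), attr(x, "peak"),
              attr(x, "peak_yaw")))
  invisible(x)
}

#' Per-word benefit along a head-yaw trajectory
#'
#' For each word window, the median over in-window trajectory samples of
#' the map benefit at the nearest grid yaw.
#'
#' @param map a [benefit_map()].
#' @param traj a [trajectory()].
#' @param windows a [word_windows()] within the trajectory time span.
#' @return numeric vector of five dB values (plus a `post` attribute with
#'   the post-final-window value when the windows carry one).
#' @export
trajectory_benefit <- function(map, traj, windows) {
  span <- range(traj$time)
  win <- windows$words
  if (any(win$onset < span[1] - 1e-9) || any(win$offset > span[2] + 1e-9))
    stop("word windows outside the trajectory time span")
  val <- vapply(seq_len(nrow(win)), function(i) {
    sel <- traj$time >= win$onset[i] & traj$time < win$offset[i]
    if (!any(sel)) stop("empty word window ", i)
    median(map_benefit(map, traj$yaw[sel]))
  }, numeric(1))
  val
}

#' Export a benefit map as TSV (+ JSON summary)
#'
#' TSV columns: `yaw`, `benefit_dB`, `in_optimal_region`. The JSON summary
#' records the peak (dB), peak yaw, margin and region bounds.
#'
#' @param map a [benefit_map()].
#' @param path_tsv output TSV path.
#' @param path_json optional JSON summary path.
#' @param margin optimal-region margin in dB.
#' @return `path_tsv`, invisibly.
#' @export
write_benefit_map <- function(map, path_tsv, path_json = NULL, margin = 1) {
  reg <- optimal_region(map, margin)
  df <- data.frame(yaw = map$yaw, benefit_dB = map$benefit,
                   in_optimal_region = map$yaw %in% as.numeric(reg))
  write.table(df, path_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(path_json)) {
    jsonlite::write_json(
      list(peak_dB = attr(reg, "peak"), peak_yaw = attr(reg, "peak_yaw"),
           margin_dB = margin, region_yaws = as.numeric(reg),
           target_azimuth = attr(map, "target_azimuth"),
           interferer_azimuth = attr(map, "interferer_azimuth")),
      path_json, auto_unbox = TRUE, digits = NA)
  }
  invisible(path_tsv)
}
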