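## Reverberation-time estimation by Schroeder backward integration.

#' Octave-band T30 from an impulse response
#'
#' Band-filters the impulse response (3rd-order Butterworth band-pass, one
#' octave wide, applied forward-backward), backward-integrates the squared
#' signal into the energy-decay curve (EDC), fits a least-squares line to
#' the EDC between -5 and -35 dB, and extrapolates to a 60 dB decay:
#' `T30 = -60 / slope`, i.e. twice the fitted -5 to -35 dB fall time.
#'
#' @param ir numeric impulse response (single channel).
#' @param sample_rate sampling rate in Hz.
#' @param octave_band band centre frequency in Hz; `NULL` skips filtering
#'   and evaluates the broadband decay.
#' @return T30 in seconds.
#' @export
schroeder_t30 <- function(ir, sample_rate, octave_band = 1000) {
  x <- as.numeric(ir)
  if (!is.null(octave_band)) {
    lo <- octave_band / sqrt(2)
    hi <- min(octave_band * sqrt(2), 0.45 * sample_rate)
    bf <- signal::butter(3, c(lo, hi) / (sample_rate / 2), type = "pass")
    x <- signal::filtfilt(bf, x)
  }
  edc <- rev(cumsum(rev(x^2)))
  if (edc[1] <= 0) stop("impulse response has no energy in this band")
  db <- 10 * log10(edc / edc[1])
  ## truncation region: the tail of the backward integral is dominated by
  ## the cut-off of the IR, not by the room decay
  n_use <- floor(0.95 * length(db))
  i5 <- which(db[seq_len(n_use)] <= -5)[1]
  i35 <- which(db[seq_len(n_use)] <= -35)[1]
  if (is.na(i5) || is.na(i35))
    stop("decay range insufficient: EDC does not reach -35 dB; ",
         "use a longer impulse response")
  idx <- i5:i35
  t <- (idx - 1) / sample_rate
  fit <- lm.fit(cbind(1, t), db[idx])
  slope <- fit$coefficients[2]
  if (slope >= 0) stop("non-decaying energy curve")
  unname(-60 / slope)
}

## ---- specular decay law and absorption calibration -------------------------
## Pure specular image-source decay in a shoebox is NOT a single
## exponential: a ray travelling along direction u crosses the x-wall
## lattice |u_x|/Lx times per metre (likewise y, z), so its energy decays
## at a direction-dependent rate. The band energy-decay curve is the
## angular average
##   EDC(t) = < exp(-lambda(u) t) / lambda(u) >,
##   lambda(u) = -ln(1 - alpha) * c * (|u_x|/Lx + |u_y|/Ly + |u_z|/Lz),
## which is slower than Eyring's diffuse-field prediction (Jensen's
## inequality), drastically so for flat rooms. Inverting THIS law yields
## absorptions whose simulated Schroeder T30 actually matches a target.

## Analytic T30 (via the -5..-35 dB least-squares fit) of the specular
## shoebox decay law for uniform absorption alpha.
ism_decay_t30 <- function(dims, alpha, speed_of_sound = SPEED_OF_SOUND,
                          n_quad = 64) {
  stopifnot(alpha > 0, alpha < 1)
  ## octant quadrature over directions, weight sin(theta)
  th <- (seq_len(n_quad) - 0.5) * (pi / 2) / n_quad
  ph <- (seq_len(n_quad) - 0.5) * (pi / 2) / n_quad
  g <- outer(th, ph, function(t, p)
    sin(t) * cos(p) / dims[1] + sin(t) * sin(p) / dims[2] +
      cos(t) / dims[3])
  w <- matrix(sin(th), n_quad, n_quad)
  lam <- -log(1 - alpha) * speed_of_sound * as.numeric(g)
  wts <- as.numeric(w) / sum(w)
  t_ref <- eyring_t30(dims, alpha, speed_of_sound)
  tt <- seq(0, 4 * t_ref, length.out = 600)
  edc <- vapply(tt, function(t0) sum(wts * exp(-lam * t0) / lam), numeric(1))
  db <- 10 * log10(edc / edc[1])
  while (db[length(db)] > -36) {        # extend if the tail is too slow
    tt <- seq(0, 2 * max(tt), length.out = 600)
    edc <- vapply(tt, function(t0) sum(wts * exp(-lam * t0) / lam),
                  numeric(1))
    db <- 10 * log10(edc / edc[1])
  }
  idx <- which(db <= -5 & db >= -35)
  fit <- lm.fit(cbind(1, tt[idx]), db[idx])
  unname(-60 / fit$coefficients[2])
}

#' Invert the specular shoebox decay law for an absorption coefficient
#'
#' Finds the uniform absorption whose image-source (specular) decay has a
#' given T30 under the -5 to -35 dB Schroeder fit. Because the specular
#' decay of a shoebox is an angular mixture of exponentials, this value is
#' larger than [eyring_alpha()]'s diffuse-field estimate, markedly so for
#' flat rooms; use it when the simulated impulse response itself must
#' reproduce a measured reverberation time.
#'
#' @inheritParams eyring_alpha
#' @return absorption coefficient in (0, 1).
#' @seealso [eyring_alpha()] for the diffuse-field (Eyring) inversion.
#' @export
calibrate_alpha <- function(dims, target_t30,
                            speed_of_sound = SPEED_OF_SOUND) {
  stopifnot(target_t30 > 0)
  a0 <- eyring_alpha(dims, target_t30, speed_of_sound)
  f <- function(a) ism_decay_t30(dims, a, speed_of_sound) - target_t30
  upper <- min(0.999, 8 * a0)
  while (f(upper) > 0 && upper < 0.999) upper <- min(0.999, upper * 1.5)
  uniroot(f, c(a0 / 2, upper), tol = 1e-6)$root
}

## ---- BRIR WAV export/import ------------------------------------------------
## 2-channel IEEE float32 WAV (RIFF); no R dependency in this environment
## provides WAV I/O, so the 44-byte canonical header is written directly.

#' Write a BRIR as a 2-channel float32 WAV file
#'
#' @param brir a `brir` object from [render_brir()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_brir_wav <- function(brir, path) {
  stopifnot(inherits(brir, "brir"))
  n <- length(brir$left)
  fs <- as.integer(brir$sample_rate)
  inter <- as.numeric(rbind(brir$left, brir$right))
  data_bytes <- 4L * length(inter)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(3L, con, size = 2, endian = "little")           # IEEE float
  writeBin(2L, con, size = 2, endian = "little")           # channels
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(fs * 8L, con, size = 4, endian = "little")      # byte rate
  writeBin(8L, con, size = 2, endian = "little")           # block align
  writeBin(32L, con, size = 2, endian = "little")          # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  writeBin(inter, con, size = 4, endian = "little")
  invisible(path)
}

#' Read a 2-channel float32 WAV file as a BRIR
#'
#' @param path file written by [write_brir_wav()] (or any 2-channel
#'   float32 PCM WAV).
#' @return a `brir` object.
#' @export
read_brir_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAV file")
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  readChar(con, 4)                                        # WAVE
  fs <- NULL; nchan <- NULL; fmt <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk found")
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, integer(), size = 2, endian = "little")
      nchan <- readBin(con, integer(), size = 2, endian = "little")
      fs <- readBin(con, integer(), size = 4, endian = "little")
      invisible(readBin(con, raw(), n = sz - 8))
    } else if (id == "data") {
      if (fmt != 3L || nchan != 2L)
        stop("expected 2-channel IEEE float32 WAV")
      x <- readBin(con, numeric(), n = sz / 4, size = 4, endian = "little")
      m <- matrix(x, nrow = 2)
      return(structure(list(left = m[1, ], right = m[2, ],
                            sample_rate = fs,
                            duration = ncol(m) / fs),
                       class = "brir"))
    } else {
      invisible(readBin(con, raw(), n = sz))
    }
  }
}
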