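brir_from <- function(left, right, fs = 44100) {
  structure(list(left = left, right = right, sample_rate = fs,
                 duration = length(left) / fs), class = "brir")
}

test_that("model constants satisfy their invariants", {
  mc <- model_constants()
  expect_equal(sum(mc$band_weights), 1, tolerance = 1e-9)
  expect_true(all(mc$band_weights >= 0))
  expect_true(all(diff(mc$band_centers) > 0))
  expect_equal(range(mc$band_centers), c(100, 8000), tolerance = 1e-6)
  mu <- model_constants(weights = "uniform")
  expect_equal(mu$band_weights, rep(1 / 16, 16))
})

test_that("band parameters: diotic input gives coherence 1 and phase 0", {
  set.seed(81)
  x <- rnorm(2048) * exp(-(1:2048) / 500)
  b <- brir_from(x, x)
  bd <- band_parameters(b, b)
  expect_true(all(abs(bd$coherence - 1) < 1e-9))
  expect_true(all(abs(bd$phase_target) < 1e-6))
  expect_true(all(abs(bd$phase_interferer) < 1e-6))
})

test_that("uncorrelated noise pairs have low interaural coherence", {
  set.seed(82)
  coh <- replicate(50, {
    b <- brir_from(rnorm(4096), rnorm(4096))
    mean(band_parameters(b, b)$coherence)
  })
  expect_lt(mean(coh), 0.2)
})

test_that("a pure interaural delay maps to the expected band phase", {
  fs <- 44100
  d <- round(500e-6 * fs)               # ~500 us in whole samples
  x <- numeric(1024); x[100] <- 1
  y <- numeric(1024); y[100 + d] <- 1
  b <- brir_from(x, y)
  bd <- band_parameters(b, b)
  i500 <- which.min(abs(bd$band - 500))
  ## sign convention: a leading left channel gives a negative lag/phase
  expect_equal(bd$phase_target[i500],
               -2 * pi * bd$band[i500] * d / fs, tolerance = 1e-6)
  expect_equal(abs(bd$coherence[i500]), 1, tolerance = 1e-6)
})

test_that("bmld matches its closed form, floors at 0, stays continuous", {
  ## k = 1.0625 * exp((2 pi 500)^2 * (105e-6)^2) at the default constants
  k <- 1.0625 * exp((2 * pi * 500)^2 * (105e-6)^2)
  expect_equal(bmld(pi, 0, 1, 500), 10 * log10((k + 1) / (k - 1)),
               tolerance = 1e-12)
  expect_equal(bmld(pi, 0, 1, 500), 10.73, tolerance = 1e-3)
  expect_equal(bmld(0.7, 0.7, 1, 500), 0)
  expect_equal(bmld(0, 0, 0, 500), 0)   # negative argument clamps to 0
  expect_error(bmld(0, 0, 1.4, 500), "coherence")
  ## continuity and non-negativity over a parameter sweep
  ph <- seq(-pi, pi, length.out = 1000)
  v <- bmld(ph, 0, 0.9, 400)
  expect_true(all(v >= 0))
  expect_lt(max(abs(diff(v))), 0.1)
  cohs <- seq(0, 1, length.out = 1000)
  v2 <- bmld(pi, 0, cohs, 400)
  expect_lt(max(abs(diff(v2))), 0.06)
})

test_that("effective TIR: identities, scale equivariance, rescaling", {
  set.seed(83)
  x <- rnorm(2048) * exp(-(1:2048) / 400)
  y <- rnorm(2048) * exp(-(1:2048) / 400)
  bt <- brir_from(x, y)
  ## identical target and interferer: 0 dB
  expect_equal(effective_tir(band_parameters(bt, bt)), 0, tolerance = 1e-9)
  ## doubling target pressure: +20 log10(2) dB exactly
  b2 <- brir_from(2 * x, 2 * y)
  expect_equal(effective_tir(band_parameters(b2, bt)), 20 * log10(2),
               tolerance = 1e-9)
  ## joint rescaling of both BRIRs leaves TIR unchanged
  set.seed(84)
  bi <- brir_from(rnorm(2048), rnorm(2048))
  t1 <- effective_tir(band_parameters(bt, bi))
  t2 <- effective_tir(band_parameters(
    brir_from(0.3 * x, 0.3 * y), brir_from(0.3 * bi$left, 0.3 * bi$right)))
  expect_equal(t1, t2, tolerance = 1e-9)
})

test_that("effective TIR of anechoic impulses matches a per-band hand computation", {
  ## single direct-path impulses: read amplitudes and delays off the
  ## rendered BRIRs, then apply the better-ear and BMLD formulas directly
  sc_t <- test_scene(alpha = 1, target_azimuth = 90)
  sc_i <- test_scene(alpha = 1, target_azimuth = 90)  # interferer at 0
  h <- head_model()
  bt <- render_brir(enumerate_images(sc_t, 1, 0.05), h, 44100,
                    duration = 0.05)
  bi <- render_brir(enumerate_images(sc_i, 2, 0.05), h, 44100,
                    duration = 0.05)
  mc <- model_constants()
  got <- effective_tir(band_parameters(bt, bi), mc)

  peak <- function(ch) {
    i <- which.max(abs(ch))
    list(amp = ch[i], t = (i - 1) / 44100)
  }
  ## band energies of a near-impulse are proportional to amp^2 in every
  ## band up to the band filtering of the rendered click, so compute the
  ## per-band energies by gammatone-weighting the channel spectra
  eband <- function(ch, fc) {
    X <- fft(c(ch, numeric(2048)))
    f <- pmin((0:(length(X) - 1)) * 44100 / length(X),
              44100 - (0:(length(X) - 1)) * 44100 / length(X))
    g <- (1 + ((f - fc) / (1.019 * 24.7 * (4.37e-3 * fc + 1)))^2)^(-4)
    sum(Mod(X)^2 * g)
  }
  k_of <- function(fc) (1 + mc$sigma_eps^2) *
    exp((2 * pi * fc)^2 * mc$sigma_delta^2)
  oracle <- sum(vapply(seq_along(mc$band_centers), function(b) {
    fc <- mc$band_centers[b]
    be <- 10 * log10(max(eband(bt$left, fc) / eband(bi$left, fc),
                         eband(bt$right, fc) / eband(bi$right, fc)))
    dt <- peak(bt$left)$t - peak(bt$right)$t
    di <- peak(bi$left)$t - peak(bi$right)$t
    k <- k_of(fc)
    bm <- max(0, 10 * log10((k - cos(2 * pi * fc * (dt - di))) / (k - 1)))
    mc$band_weights[b] * (be + bm)
  }, numeric(1)))
  expect_equal(got, oracle, tolerance = 0.1)
})

test_that("benefit maps: co-located flatness and mirror symmetry", {
  ## co-located target and interferer, anechoic: flat at ~0 dB
  sc <- test_scene(alpha = 1, target_azimuth = 0, interferer_azimuth = 0)
  expect_message(
    m0 <- benefit_map(sc, grid_step = 60, time_limit = 0.02,
                      sample_rate = 16000),
    "co-located")
  expect_true(all(abs(m0$benefit) < 0.1))

  ## anechoic left/right mirrored targets: mirrored maps
  mr <- benefit_map(test_scene(1, 90), grid_step = 30, time_limit = 0.02,
                    sample_rate = 16000)
  ml <- benefit_map(test_scene(1, -90), grid_step = 30, time_limit = 0.02,
                    sample_rate = 16000)
  mirrored <- ml$benefit[match((360 - mr$yaw) %% 360, ml$yaw)]
  expect_equal(mr$benefit, mirrored, tolerance = 1e-6)
})

test_that("reverberation does not raise the achievable peak benefit", {
  peak_at <- function(alpha) {
    sc <- test_scene(alpha = alpha, target_azimuth = 90)
    tl <- if (alpha == 1) 0.02 else 0.12
    max(benefit_map(sc, grid_step = 45, time_limit = tl,
                    sample_rate = 16000)$benefit)
  }
  p_anech <- peak_at(1)
  for (al in c(0.5, 0.25)) expect_lt(peak_at(al), p_anech + 1e-6)
})

test_that("optimal region picks yaws within the margin of the peak", {
  toy <- structure(data.frame(yaw = c(0, 72, 144, 216, 288),
                              benefit = c(0, 2, 5, 4.2, 1)),
                   class = c("benefit_map", "data.frame"), grid_step = 72)
  reg <- optimal_region(toy, margin = 1)
  expect_equal(as.numeric(reg), c(144, 216))
  expect_equal(attr(reg, "peak"), 5)
  reg0 <- optimal_region(toy, margin = 0)
  expect_equal(as.numeric(reg0), 144)
  flat <- structure(data.frame(yaw = toy$yaw, benefit = rep(2, 5)),
                    class = c("benefit_map", "data.frame"), grid_step = 72)
  expect_equal(as.numeric(optimal_region(flat, 1)), toy$yaw)
})

test_that("trajectory benefit reduces to map lookups for simple motions", {
  map <- structure(data.frame(yaw = 0:359,
                              benefit = sin(deg2rad(0:359)) * 3),
                   class = c("benefit_map", "data.frame"), grid_step = 1)
  t <- (0:999) / 358.6
  ww <- word_windows(onsets = seq(0.2, 2.2, by = 0.5),
                     offsets = seq(0.2, 2.2, by = 0.5) + 0.4)
  ## constant trajectory
  trc <- trajectory(t, rep(37, 1000))
  expect_equal(trajectory_benefit(map, trc, ww),
               rep(map$benefit[38], 5), tolerance = 1e-12)
  ## step exactly at a word boundary
  step_y <- ifelse(t < ww$words$onset[3], 10, 60)
  med <- trajectory_benefit(map, trajectory(t, step_y), ww)
  expect_equal(med[1:2], rep(map$benefit[11], 2))
  expect_equal(med[3:5], rep(map$benefit[61], 3))
  ## ramp across a monotone map region gives monotone word medians
  ramp <- trajectory(t, seq(0, 80, length.out = 1000))
  expect_true(all(diff(trajectory_benefit(map, ramp, ww)) > 0))
  ## dense numerical evaluation agrees with the median of lookups
  w1 <- t >= ww$words$onset[1] & t < ww$words$offset[1]
  expect_equal(trajectory_benefit(map, ramp, ww)[1],
               median(map_benefit(map, ramp$yaw[w1])))
})

test_that("benefit map TSV/JSON export round-trips", {
  toy <- structure(data.frame(yaw = c(0, 90, 180, 270),
                              benefit = c(0, 3, 5, 2)),
                   class = c("benefit_map", "data.frame"), grid_step = 90,
                   target_azimuth = 90, interferer_azimuth = 0)
  ft <- tempfile(fileext = ".tsv"); fj <- tempfile(fileext = ".json")
  write_benefit_map(toy, ft, fj)
  tab <- read.delim(ft)
  expect_equal(tab$benefit_dB, toy$benefit)
  expect_equal(tab$in_optimal_region, c(FALSE, FALSE, TRUE, FALSE))
  js <- jsonlite::read_json(fj, simplifyVector = TRUE)
  expect_equal(js$peak_dB, 5)
  expect_equal(js$peak_yaw, 180)
  unlink(c(ft, fj))
})
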