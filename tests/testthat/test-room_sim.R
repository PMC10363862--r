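test_that("scene construction validates geometry and absorption", {
  expect_error(room_scene(c(3, 4, 2.5), c(`1000` = 0.3), c(5, 1, 1),
                          data.frame(azimuth = 0, distance = 1)),
               "inside")
  expect_error(room_scene(c(3, 4, 2.5), c(`1000` = 1.2), c(1, 1, 1),
                          data.frame(azimuth = 0, distance = 0.5)),
               "absorption")
  expect_error(room_scene(c(3, 4, 2.5), c(`1000` = 0.3), c(1, 1, 1),
                          data.frame(azimuth = 0, distance = -1)),
               "distance")
  ## source pushed through a wall
  expect_error(room_scene(c(3, 4, 2.5), c(`1000` = 0.3), c(1, 2, 1),
                          data.frame(azimuth = 0, distance = 5)),
               "sources")
})

test_that("anechoic enumeration keeps only the direct path", {
  sc <- test_scene(alpha = 1)
  im <- enumerate_images(sc, 1, 0.3)
  expect_equal(length(im$dist), 1L)
  expect_equal(im$n_refl, 0L)
  expect_equal(drop(im$positions), unname(sc$source_positions[1, ]),
               tolerance = 1e-12)
  expect_equal(drop(image_attenuation(im)), rep(1, 5),
               ignore_attr = TRUE)
})

test_that("cubic room with central source yields 7 first-order images", {
  bands <- c(1000)
  sc <- room_scene(c(2, 2, 2), c(`1000` = 0.5), c(1, 1, 1.2),
                   data.frame(azimuth = 180, distance = 0.2))
  ## source at (0.8, 1, 1.2); pick a time limit covering first-order
  ## paths (< 4.3 m here) but no second-order path (> 4.4 m)
  d_first <- 4.3 / sc$speed_of_sound
  im <- enumerate_images(sc, 1, d_first)
  expect_equal(sum(im$n_refl == 0), 1L)
  expect_equal(sum(im$n_refl == 1), 6L)
  ## first-order positions come from single-plane mirroring
  p <- sc$source_positions[1, ]
  mirrors <- rbind(c(-p[1], p[2], p[3]), c(4 - p[1], p[2], p[3]),
                   c(p[1], -p[2], p[3]), c(p[1], 4 - p[2], p[3]),
                   c(p[1], p[2], -p[3]), c(p[1], p[2], 4 - p[3]))
  got <- im$positions[im$n_refl == 1, ]
  expect_equal(got[order(got[, 1], got[, 2], got[, 3]), ],
               mirrors[order(mirrors[, 1], mirrors[, 2], mirrors[, 3]), ],
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("lattice enumeration matches brute-force mirroring to order 3", {
  sc <- test_scene(alpha = 0.3)
  im <- enumerate_images(sc, 1, 0.25)
  keep <- im$n_refl <= 3
  mine <- data.frame(x = im$positions[keep, 1], y = im$positions[keep, 2],
                     z = im$positions[keep, 3], order = im$n_refl[keep])
  oracle <- brute_force_images(sc$dims, sc$source_positions[1, ], 3)
  ## oracle is unlimited in distance; restrict to the same radius
  L <- sc$listener_position
  d <- sqrt((oracle$x - L[1])^2 + (oracle$y - L[2])^2 + (oracle$z - L[3])^2)
  oracle <- oracle[d <= sc$speed_of_sound * 0.25, ]
  mine$att <- image_attenuation(im)[keep, "1000"]
  perm_m <- order(mine$x, mine$y, mine$z)
  perm_o <- order(oracle$x, oracle$y, oracle$z)
  mine <- mine[perm_m, ]; oracle <- oracle[perm_o, ]
  expect_equal(nrow(mine), nrow(oracle))
  expect_equal(mine$x, oracle$x, tolerance = 1e-9)
  expect_equal(mine$y, oracle$y, tolerance = 1e-9)
  expect_equal(mine$z, oracle$z, tolerance = 1e-9)
  expect_equal(mine$order, oracle$order)
  ## band attenuation: r^order with r = sqrt(1 - alpha), image for image
  expect_equal(mine$att, sqrt(0.7)^oracle$order, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("image count approaches the volumetric density law", {
  sc <- default_scene(90)
  tl <- 0.5   # 171 m radius: ample for the asymptotic count, fast to run
  im <- enumerate_images(sc, 1, tl)
  r <- sc$speed_of_sound * tl
  expected <- 4 / 3 * pi * r^3 / prod(sc$dims)
  expect_lt(abs(length(im$dist) - expected) / expected, 0.02)
})

test_that("rendering is symmetric for a midline source and lateralised otherwise", {
  sc <- test_scene(alpha = 1, target_azimuth = 0)
  im <- enumerate_images(sc, 1, 0.05)
  b <- render_brir(im, head_model(), 44100)
  expect_equal(b$left, b$right, tolerance = 1e-12)

  sc2 <- test_scene(alpha = 1, target_azimuth = 90)
  b2 <- render_brir(enumerate_images(sc2, 1, 0.05), head_model(), 44100)
  expect_gt(sum(b2$right^2), sum(b2$left^2))
})

test_that("direct-path delay and 1/d amplitude law hold", {
  mk <- function(d) {
    bands <- c(1000)
    sc <- room_scene(c(20, 20, 6), c(`1000` = 1), c(9, 10, 1.8),
                     data.frame(azimuth = 0, distance = d))
    render_brir(enumerate_images(sc, 1, 0.1), head_model(), 44100)
  }
  b1 <- mk(1); b2 <- mk(2); b4 <- mk(4)
  pk <- function(b) max(abs(b$left))
  expect_equal(pk(b1) / pk(b2), 2, tolerance = 0.05)
  expect_equal(pk(b2) / pk(b4), 2, tolerance = 0.05)
  ## delay of the 2.1 m case ~ 6.12 ms plus a small ear offset
  sc <- room_scene(c(20, 20, 6), c(`1000` = 1), c(9, 10, 1.8),
                   data.frame(azimuth = 0, distance = 2.1))
  b <- render_brir(enumerate_images(sc, 1, 0.1), head_model(), 44100)
  t_peak <- (which.max(abs(b$left)) - 1) / 44100
  expect_equal(t_peak, 2.1 / 343, tolerance = 0.02)
})

test_that("mirror-symmetric scenes swap ears exactly (anechoic)", {
  b_r <- render_brir(enumerate_images(test_scene(1, 90), 1, 0.05),
                     head_model(), 44100)
  b_l <- render_brir(enumerate_images(test_scene(1, -90), 1, 0.05),
                     head_model(), 44100)
  expect_equal(b_r$left, b_l$right, tolerance = 1e-12)
  expect_equal(b_r$right, b_l$left, tolerance = 1e-12)
})

test_that("render_brir rejects empty or invalid input", {
  sc <- test_scene(1)
  im <- enumerate_images(sc, 1, 0.05)
  im2 <- im; im2$dist <- numeric(0)
  expect_error(render_brir(im2, head_model()), "empty")
  expect_error(render_brir(im, head_model(), sample_rate = 8000), "16 kHz")
})

test_that("schroeder_t30 recovers the decay of an exponential envelope", {
  set.seed(7)
  fs <- 16000
  tau <- 0.2
  t <- seq(0, 2.5, by = 1 / fs)
  ir <- rnorm(length(t)) * exp(-t / tau)
  expect_equal(schroeder_t30(ir, fs, 1000), 6.9078 * tau, tolerance = 0.04)
  ## broadband evaluation agrees too
  expect_equal(schroeder_t30(ir, fs, NULL), 6.9078 * tau, tolerance = 0.04)
  ## time reversal preserves total band energy (backward-integral start)
  bf <- signal::butter(3, c(1000 / sqrt(2), 1000 * sqrt(2)) / (fs / 2),
                       type = "pass")
  e_fwd <- sum(signal::filtfilt(bf, ir)^2)
  e_rev <- sum(signal::filtfilt(bf, rev(ir))^2)
  expect_equal(e_fwd, e_rev, tolerance = 0.01)   # filter edge transients
  ## too-short IR cannot reach -35 dB
  expect_error(schroeder_t30(ir[1:800], fs, 1000), "-35 dB")
})

test_that("eyring inversion round-trips and vanishes for long T30", {
  dims <- c(11, 13, 3)
  a <- eyring_alpha(dims, 1.15)
  expect_equal(eyring_t30(dims, a), 1.15, tolerance = 1e-12)
  ## root-finding oracle for the same equation
  f <- function(al) eyring_t30(dims, al) - 1.15
  a_or <- uniroot(f, c(1e-6, 0.999), tol = 1e-10)$root
  expect_equal(a, a_or, tolerance = 1e-6)
  expect_lt(eyring_alpha(dims, 1e5), 1e-5)
  expect_error(eyring_alpha(dims, 1e-9), "absorption")
})

test_that("simulated decay matches the specular shoebox decay law", {
  ## the rendered IR's Schroeder T30 should agree with the analytic
  ## angular-average decay law of the image model (Eyring's diffuse
  ## formula underestimates specular shoebox decay, especially in flat
  ## rooms, so it is not the right oracle here)
  for (al in c(0.25, 0.45)) {
    sc <- test_scene(alpha = al)
    t_law <- rotaspeech:::ism_decay_t30(sc$dims, al)
    im <- enumerate_images(sc, 1, 1.4 * t_law)
    ir <- render_rir(im, sample_rate = 44100)
    t30 <- schroeder_t30(ir, 44100, 2000)
    expect_lt(abs(t30 - t_law) / t_law, 0.10)
  }
})

test_that("calibrated absorption reproduces a target T30 analytically", {
  dims <- c(11, 13, 3)
  a <- calibrate_alpha(dims, 1.15)
  expect_gt(a, eyring_alpha(dims, 1.15))   # specular decay is slower
  expect_equal(rotaspeech:::ism_decay_t30(dims, a), 1.15,
               tolerance = 0.005)
})

test_that("BRIR WAV export round-trips", {
  sc <- test_scene(0.5)
  b <- render_brir(enumerate_images(sc, 1, 0.04), head_model(), 44100)
  f <- tempfile(fileext = ".wav")
  write_brir_wav(b, f)
  b2 <- read_brir_wav(f)
  expect_equal(b2$sample_rate, 44100)
  expect_equal(b2$left, b$left, tolerance = 1e-6)
  expect_equal(b2$right, b$right, tolerance = 1e-6)
  unlink(f)
})

test_that("scene YAML/JSON configuration round-trips", {
  sc <- test_scene(0.4)
  cfg <- list(dims = sc$dims,
              absorption = as.list(setNames(sc$band_absorption,
                                            sc$band_freqs)),
              listener = sc$listener_position,
              sources = list(list(azimuth = 90, distance = 0.9, level = 60),
                             list(azimuth = 0, distance = 0.9, level = 70)))
  fy <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, fy)
  sc2 <- read_scene(fy)
  expect_equal(sc2$dims, sc$dims)
  expect_equal(sc2$band_absorption, sc$band_absorption, ignore_attr = TRUE)
  expect_equal(sc2$source_positions, sc$source_positions,
               tolerance = 1e-12, ignore_attr = TRUE)
  fj <- tempfile(fileext = ".json")
  jsonlite::write_json(cfg, fj, auto_unbox = TRUE, digits = NA)
  sc3 <- read_scene(fj)
  expect_equal(sc3$dims, sc$dims)
  unlink(c(fy, fj))
})
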