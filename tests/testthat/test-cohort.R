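test_that("design balance holds for every seed", {
  cfg <- cohort_config()
  for (seed in c(1, 7, 1234)) {
    set.seed(seed)
    des <- make_design(cfg)
    expect_equal(nrow(des), 288)
    ## 12 trials per location in every block
    tab <- table(des$block, des$target)
    expect_true(all(tab == 12))
    ## each condition in exactly two blocks; first three cover all three
    cond_by_block <- unique(des[c("block", "condition")])$condition
    expect_equal(sort(table(cond_by_block)), sort(c(2, 2, 2)),
                 ignore_attr = TRUE)
    expect_setequal(cond_by_block[1:3], cfg$conditions)
  }
  ## different seeds give different orderings with identical margins
  set.seed(1); d1 <- make_design(cfg)
  set.seed(2); d2 <- make_design(cfg)
  expect_false(identical(d1$target, d2$target))
  expect_equal(table(d1$target), table(d2$target))
})

test_that("word windows have the configured duration distribution", {
  cfg <- cohort_config()
  set.seed(101)
  draws <- replicate(1e4, {
    ww <- gen_word_windows(cfg)
    c(dur = ww$words$offset[5] - ww$words$onset[1],
      onset = ww$words$onset[1])
  })
  dur <- draws["dur", ]
  expect_equal(mean(dur), 2.19, tolerance = 0.02 / 2.19)
  expect_true(all(dur >= 1.78 - 1e-9 & dur <= 2.77 + 1e-9))
  expect_true(all(draws["onset", ] == cfg$target_onset))
  ## windows partition the sentence exactly
  set.seed(102)
  ww <- gen_word_windows(cfg)
  expect_equal(ww$words$onset[-1], ww$words$offset[-5], tolerance = 1e-12)
})

test_that("static trajectories respect the 3-degree tolerance", {
  cfg <- cohort_config()
  set.seed(111)
  for (i in 1:20) {
    tr <- gen_trajectory("Static", sample(cfg$targets, 1), cfg)
    expect_true(all(abs(tr$yaw) <= 3))
  }
})

test_that("moving trajectories undershoot as configured and cap speed", {
  cfg <- cohort_config()
  set.seed(121)
  finals <- replicate(1000, {
    tr <- gen_trajectory("A-only", -90, cfg)
    median(tr$yaw[tr$time > max(tr$time) - 0.3])
  })
  ## final orientation re target: circular median ~ +29 deg (undershoot)
  expect_equal(circ_median(finals) - (-90), 29, tolerance = 0.15 * 29)

  ## peak angular speed never exceeds the cap (by construction)
  set.seed(122)
  for (i in 1:20) {
    tr <- gen_trajectory(sample(c("A-only", "AV"), 1),
                         sample(c(-90, 90, 180), 1), cfg)
    v <- diff(tr$yaw) * tr$rate
    expect_lte(max(abs(v)), cfg$peak_speed * 1.02 + 5)
  }

  ## rear turns go left or right about equally
  set.seed(123)
  sides <- replicate(400, {
    tr <- gen_trajectory("AV", 180, cfg)
    sign(tr$yaw[length(tr$yaw)])
  })
  expect_gt(mean(sides > 0), 0.4)
  expect_lt(mean(sides > 0), 0.6)
})

test_that("AV final orientations are tighter than A-only", {
  cfg <- cohort_config()
  set.seed(131)
  fin <- function(cond) replicate(400, {
    tr <- gen_trajectory(cond, -90, cfg)
    median(tr$yaw[tr$time > max(tr$time) - 0.3])
  })
  expect_lt(circ_variance(fin("AV")), circ_variance(fin("A-only")))
})

test_that("response generation follows the psychometric truth", {
  cfg <- cohort_config(delta = 1.4)
  set.seed(141)
  tr <- gen_trajectory("Static", 0, cfg)
  win <- gen_word_windows(cfg)
  trial <- list(condition = "Static", trajectory = tr, windows = win)
  ## benefit at the psychometric midpoint: p = 0.5
  mid <- -cfg$beta0 / cfg$beta1
  flags <- replicate(2000, gen_responses(trial, rep(mid, 5), 0, cfg))
  expect_equal(mean(flags), 0.5, tolerance = 0.025)
  ## Static trials are unaffected by the deficit (no motion)
  p_expected <- plogis(cfg$beta0 + cfg$beta1 * 2)
  flags2 <- replicate(2000, gen_responses(trial, rep(2, 5), 0, cfg))
  expect_equal(mean(flags2), p_expected, tolerance = 0.025)
  ## a moving word is penalised by delta
  trm <- gen_trajectory("A-only", -90, cfg)
  mov_trial <- list(condition = "A-only", trajectory = trm, windows = win)
  r <- gen_responses(mov_trial, rep(2, 5), 0, cfg)
  expect_true(any(attr(r, "moving")))
  i <- which(attr(r, "moving"))[1]
  expect_equal(attr(r, "p")[i], plogis(cfg$beta0 + cfg$beta1 * (2 - 1.4)),
               tolerance = 1e-9)
})

test_that("cohorts are reproducible from the seed and sized correctly", {
  cfg <- cohort_config(n_participants = 2, seed = 7)
  t1 <- gen_cohort(cfg, conditions = "Static")
  t2 <- gen_cohort(cfg, conditions = "Static")
  expect_identical(t1, t2)
  expect_equal(length(t1), 2 * 96)       # 2 blocks x 48 Static trials
  expect_error(gen_cohort(cfg), "benefit_maps")

  ## default size matches the study: 9 participants x 288 trials
  cfg9 <- cohort_config()
  expect_equal(cfg9$n_participants, 9)
  expect_equal(cfg9$beta1 / 4, 0.08)

  ## export writes the three cohort files
  dir <- tempfile()
  write_cohort(t1, dir)
  expect_true(all(file.exists(file.path(dir,
    c("trajectories.csv", "trials.tsv", "config.yaml")))))
  tab <- read.delim(file.path(dir, "trials.tsv"))
  expect_equal(nrow(tab), length(t1))
  cfg_back <- yaml::read_yaml(file.path(dir, "config.yaml"))
  expect_equal(cfg_back$seed, 7)
  unlink(dir, recursive = TRUE)
})
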