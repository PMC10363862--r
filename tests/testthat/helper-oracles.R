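## Independent oracles and shared fixtures, built in code at test time.

## Brute-force image-source oracle: mirror the source recursively across
## the six wall planes (never the same plane twice in a row), collecting
## unique image positions with their minimal reflection count. Independent
## of the lattice construction used by enumerate_images().
brute_force_images <- function(dims, source, max_order) {
  planes <- list(
    function(p) c(-p[1], p[2], p[3]),
    function(p) c(2 * dims[1] - p[1], p[2], p[3]),
    function(p) c(p[1], -p[2], p[3]),
    function(p) c(p[1], 2 * dims[2] - p[2], p[3]),
    function(p) c(p[1], p[2], -p[3]),
    function(p) c(p[1], p[2], 2 * dims[3] - p[3]))
  key <- function(p) paste(sprintf("%.9f", p), collapse = ",")
  found <- new.env(parent = emptyenv())
  assign(key(source), list(pos = source, order = 0L), envir = found)
  frontier <- list(list(pos = source, last = 0L))
  for (ord in seq_len(max_order)) {
    nxt <- list()
    for (node in frontier) {
      for (pl in seq_along(planes)) {
        if (pl == node$last) next
        q <- planes[[pl]](node$pos)
        k <- key(q)
        if (!exists(k, envir = found, inherits = FALSE)) {
          assign(k, list(pos = q, order = ord), envir = found)
        }
        nxt[[length(nxt) + 1]] <- list(pos = q, last = pl)
      }
    }
    frontier <- nxt
  }
  items <- mget(ls(found), envir = found)
  data.frame(x = vapply(items, function(i) i$pos[1], 0),
             y = vapply(items, function(i) i$pos[2], 0),
             z = vapply(items, function(i) i$pos[3], 0),
             order = vapply(items, function(i) i$order, 0L))
}

## Small generic test room with uniform absorption.
test_scene <- function(alpha = 0.3, target_azimuth = 90,
                       interferer_azimuth = 0) {
  bands <- c(250, 500, 1000, 2000, 4000)
  room_scene(
    dims = c(3.2, 4.1, 2.6),
    band_absorption = setNames(rep(alpha, length(bands)), bands),
    listener_position = c(1.4, 1.9, 1.25),
    sources = data.frame(azimuth = c(target_azimuth, interferer_azimuth),
                         distance = c(0.9, 0.9), level = c(60, 70)))
}

## von Mises sampler (Best & Fisher rejection scheme), angles in degrees.
rvonmises_deg <- function(n, mu_deg = 0, kappa = 2) {
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 0
  while (i < n) {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
      i <- i + 1
      out[i] <- sign(u[3] - 0.5) * acos(f)
    }
  }
  (mu_deg + out * 180 / pi) %% 360
}

## Low-resolution benefit maps shared across the cohort/pipeline tests:
## coarse grid and short image limit keep them cheap while retaining the
## lateral/rear structure. Built once per test run.
.test_map_cache <- new.env(parent = emptyenv())
test_maps <- function() {
  if (!is.null(.test_map_cache$maps)) return(.test_map_cache$maps)
  maps <- lapply(c(`0` = 0, `-90` = -90, `90` = 90, `180` = 180),
                 function(az)
    benefit_map(default_scene(az), grid_step = 5, time_limit = 0.06,
                sample_rate = 16000))
  .test_map_cache$maps <- maps
  maps
}

## A small cohort config for pipeline tests (fewer participants).
small_config <- function(...) {
  cohort_config(n_participants = 4, seed = 42, ...)
}
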