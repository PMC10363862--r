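## Small angle / random-variate helpers shared across modules.
## Convention everywhere: angles in degrees, 0 = facing direction,
## positive clockwise seen from above (rightward); wrapped to (-180, 180].

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap angles to (-180, 180] degrees
#'
#' @param x numeric vector of angles in degrees.
#' @return angles wrapped to the half-open interval (-180, 180].
#' @export
wrap_angle <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

#' Unwrap an angle series
#'
#' Removes jumps larger than 180 degrees between consecutive samples so the
#' series becomes continuous (e.g. +179 to -179 becomes +179 to +181).
#'
#' @param x numeric vector of angles in degrees.
#' @return unwrapped series, same length.
#' @export
unwrap_deg <- function(x) {
  if (length(x) < 2) return(x)
  d <- diff(x)
  jump <- -round(d / 360) * 360
  x + c(0, cumsum(jump))
}

## Truncated normal draw by inverse-CDF; vectorised over n.
rtruncnorm1 <- function(n, mean, sd, lower, upper) {
  pl <- pnorm(lower, mean, sd)
  pu <- pnorm(upper, mean, sd)
  qnorm(runif(n, pl, pu), mean, sd)
}

## Mean of a truncated normal (closed form).
truncnorm_mean <- function(mean, sd, lower, upper) {
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  mean + sd * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
}

## Dirichlet draw (single vector) via gamma normalisation.
rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
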