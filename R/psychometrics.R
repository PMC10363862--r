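## RAU transform and the random-intercept logistic psychometric model that
## maps model-predicted benefit (dB) to proportion of words correct.

#' Rationalized arcsine units (RAU)
#'
#' Studebaker's linearized transform of a correct count out of `n`:
#' `theta = asin(sqrt(x / (n + 1))) + asin(sqrt((x + 1) / (n + 1)))`,
#' `RAU = (146 / pi) * theta - 23`. Behaves like a percent scale in the
#' midrange (RAU(12, 24) is exactly 50) while stabilising the variance at
#' the extremes.
#'
#' @param n_correct integer count(s) of correct answers, `0 <= x <= n`.
#' @param n_total total answers per cell (default 24).
#' @return RAU value(s).
#' @export
rau <- function(n_correct, n_total = 24) {
  stopifnot(all(n_correct >= 0), all(n_correct <= n_total), all(n_total >= 1))
  th <- asin(sqrt(n_correct / (n_total + 1))) +
    asin(sqrt((n_correct + 1) / (n_total + 1)))
  (146 / pi) * th - 23
}

#' Fit the random-intercept logistic psychometric function
#'
#' Generalized linear random-effects (GLRE) fit of binomial word counts on
#' model-predicted benefit: `logit(p) = beta0 + beta1 * dB + u_j` with a
#' per-participant random intercept `u_j`, estimated by maximum likelihood
#' (Laplace approximation, via `lme4::glmer`).
#'
#' @param scores data.frame with columns `participant`, `predicted_db`,
#'   `n_correct`, `n_total`; at least two participants and two distinct
#'   predictor values.
#' @return object of class `psych_fit`: `beta0`, `beta1`, `slope`
#'   (`beta1 / 4`, the maximum slope of the psychometric function in
#'   proportion per dB), `ranef` (named per-participant intercepts),
#'   `sigma_u`, and the underlying `model`.
#' @export
fit_glre <- function(scores) {
  need <- c("participant", "predicted_db", "n_correct", "n_total")
  stopifnot(all(need %in% names(scores)))
  if (length(unique(scores$predicted_db)) < 2)
    stop("need at least two distinct predicted-dB values")
  if (length(unique(scores$participant)) < 2)
    stop("need at least two participants")
  scores$participant <- factor(scores$participant)
  fit <- tryCatch(
    suppressMessages(lme4::glmer(
      cbind(n_correct, n_total - n_correct) ~ predicted_db + (1 | participant),
      data = scores, family = stats::binomial())),
    error = function(e) e)
  if (inherits(fit, "error")) {
    ## the mixed fit degenerates when the random-intercept variance sits
    ## on the zero boundary (e.g. noise-free data); fall back to the
    ## pooled logistic, which is the same model with u_j = 0
    pooled <- tryCatch(
      stats::glm(cbind(n_correct, n_total - n_correct) ~ predicted_db,
                 data = scores, family = stats::binomial()),
      error = function(e) stop("GLRE fit failed: ", conditionMessage(e)))
    b <- coef(pooled)
    if (any(!is.finite(b)) || abs(b[2]) > 50)
      stop("GLRE fit degenerate (separation?): slope not identifiable")
    u <- setNames(rep(0, nlevels(scores$participant)),
                  levels(scores$participant))
    return(structure(list(beta0 = unname(b[1]), beta1 = unname(b[2]),
                          slope = unname(b[2]) / 4, ranef = u,
                          sigma_u = 0, model = pooled),
                     class = "psych_fit"))
  }
  b <- lme4::fixef(fit)
  if (any(!is.finite(b)) || abs(b[2]) > 50)
    stop("GLRE fit degenerate (separation?): slope not identifiable")
  re <- lme4::ranef(fit)$participant
  u <- setNames(re[[1]], rownames(re))
  structure(list(beta0 = unname(b[1]), beta1 = unname(b[2]),
                 slope = unname(b[2]) / 4, ranef = u,
                 sigma_u = sqrt(unname(lme4::VarCorr(fit)$participant[1])),
                 model = fit),
            class = "psych_fit")
}

#' @export
print.psych_fit <- function(x, ...) {
  cat(sprintf(
    "psych_fit: logit(p) = %.3f + %.3f * dB + u_j (max slope %.3f /dB, sigma_u %.3f)\n",
    x$beta0, x$beta1, x$slope, x$sigma_u))
  invisible(x)
}

#' Predict proportion correct and RAU from a psychometric fit
#'
#' Inverse-logit at `beta0 + beta1 * dB + u_j`; unknown participants fall
#' back to the population curve (`u = 0`) with a `population` flag. The
#' RAU value is that of the implied expected count on `n_total` answers.
#'
#' @param fit a [fit_glre()] result.
#' @param benefit_db numeric benefit(s) in dB.
#' @param participant participant id (optional).
#' @param n_total answers per cell for the RAU conversion (default 24).
#' @return data.frame with `proportion`, `rau`, `population`.
#' @export
predict_score <- function(fit, benefit_db, participant = NULL, n_total = 24) {
  stopifnot(inherits(fit, "psych_fit"))
  u <- 0
  population <- TRUE
  if (!is.null(participant)) {
    id <- as.character(participant)
    if (id %in% names(fit$ranef)) {
      u <- fit$ranef[[id]]
      population <- FALSE
    }
  }
  p <- plogis(fit$beta0 + fit$beta1 * benefit_db + u)
  data.frame(proportion = p, rau = rau(p * n_total, n_total),
             population = population)
}

#' Convert a RAU-scale error to dB via the psychometric slope
#'
#' Treats RAU as a percent-like scale near midrange, so an error of
#' `e` RAU corresponds to `e / (100 * slope)` dB for a maximum slope in
#' proportion per dB (11 RAU at slope 0.08/dB is about 1.4 dB).
#'
#' @param error_rau error in RAU.
#' @param slope_per_db maximum psychometric slope, proportion per dB (> 0).
#' @return equivalent error in dB.
#' @export
rau_error_to_db <- function(error_rau, slope_per_db) {
  stopifnot(slope_per_db > 0)
  error_rau / (100 * slope_per_db)
}

#' Build per-cell score tables from trial records
#'
#' Aggregates word-correct flags into cells of condition x target x word
#' position per participant: `n_correct` out of `n_total` answers, with
#' percent and RAU columns.
#'
#' @param trials list of trial records (see [gen_cohort()]).
#' @return data.frame of score cells.
#' @export
score_cells <- function(trials) {
  rows <- lapply(trials, function(tr)
    data.frame(participant = tr$participant, condition = tr$condition,
               target = tr$target, word = 1:5,
               correct = as.integer(tr$words_correct)))
  df <- do.call(rbind, rows)
  agg <- aggregate(correct ~ participant + condition + target + word,
                   df, function(x) c(k = sum(x), n = length(x)))
  out <- data.frame(participant = agg$participant, condition = agg$condition,
                    target = agg$target, word = agg$word,
                    n_correct = agg$correct[, "k"],
                    n_total = agg$correct[, "n"])
  out$percent <- 100 * out$n_correct / out$n_total
  out$rau <- rau(out$n_correct, out$n_total)
  out
}
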