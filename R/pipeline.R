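## Orchestration: simulate -> analyze -> report on synthetic cohorts.

#' Simulate a cohort and its benefit maps, writing all files
#'
#' Builds the four scene configurations (target at 0, -90, +90, 180 deg
#' with the interferer at 0 deg), computes their head-orientation benefit
#' maps, generates a synthetic cohort driven by those maps, and writes
#' maps (TSV + JSON), cohort files and a run log to `out_dir`.
#'
#' @param out_dir output directory.
#' @param config a [cohort_config()]; its seed drives all randomness.
#' @param map_args list of arguments forwarded to [benefit_map()]
#'   (e.g. `time_limit`, `sample_rate`, `grid_step`) -- lower-resolution
#'   settings make exploratory runs fast.
#' @param scenes optional prebuilt named list of scenes keyed by target
#'   azimuth; defaults to [default_scene()] per target.
#' @return invisibly, a list with `trials`, `maps` and `paths`.
#' @export
run_simulate <- function(out_dir, config = cohort_config(),
                         map_args = list(), scenes = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  targets <- config$targets
  if (is.null(scenes))
    scenes <- setNames(lapply(targets, default_scene), as.character(targets))
  maps <- lapply(scenes, function(sc)
    do.call(benefit_map, c(list(scene = sc), map_args)))
  paths <- character()
  for (nm in names(maps)) {
    pt <- file.path(out_dir, sprintf("benefit_map_%s.tsv", nm))
    pj <- file.path(out_dir, sprintf("benefit_map_%s.json", nm))
    write_benefit_map(maps[[nm]], pt, pj)
    paths <- c(paths, pt, pj)
  }
  trials <- gen_cohort(config, benefit_maps = maps)
  write_cohort(trials, out_dir)
  log <- list(package_version = as.character(packageVersion("rotaspeech")),
              seed = config$seed,
              config_hash = config_hash(config),
              n_trials = length(trials))
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(trials = trials, maps = maps,
                 paths = c(paths, file.path(out_dir, "trials.tsv"))))
}

config_hash <- function(config) {
  x <- unlist(unclass(config))
  sum(utf8ToInt(paste(names(x), format(x), collapse = "|")) *
        seq_along(utf8ToInt(paste(names(x), format(x), collapse = "|")))) %%
    .Machine$integer.max
}

#' Analyze a cohort: behaviour, psychometrics, model comparison
#'
#' Produces the full report bundle on a cohort of trial records:
#' \itemize{
#'   \item per-word orientation summaries and optimal-region occupancy;
#'   \item final-word circular summaries plus AV vs A-only Kuiper tests
#'     per target;
#'   \item per-word intelligibility and model predictions in RAU;
#'   \item repeated-measures ANOVA tables: the full three-factor model,
#'     the four two-factor contrasts (Static vs A-only and AV vs A-only,
#'     lateral and rear), and the model-vs-data comparison;
#'   \item the mean signed model-minus-data error in RAU and dB, and the
#'     dynamic-deficit estimate restricted to words spoken in motion.
#' }
#'
#' @param trials list of trial records from [gen_cohort()].
#' @param maps named list of [benefit_map()]s keyed by target azimuth (as
#'   used to analyse the trajectories; may be the generating maps).
#' @param config the [cohort_config()] (for target onset, thresholds).
#' @param out_dir optional directory; when given, every table is written
#'   as TSV/JSON.
#' @param n_permutations permutations for the Kuiper tests.
#' @return list of class `rota_report`.
#' @export
run_analyze <- function(trials, maps, config = attr(trials, "config"),
                        out_dir = NULL, n_permutations = 2000) {
  if (is.null(config)) config <- cohort_config()
  conds <- unique(vapply(trials, `[[`, character(1), "condition"))

  ## ---- per-trial per-word quantities --------------------------------------
  word_tab <- do.call(rbind, lapply(trials, function(tr) {
    med <- per_word_orientation(tr$trajectory, tr$windows)
    hob <- trajectory_benefit(maps[[as.character(tr$target)]],
                              tr$trajectory, tr$windows)
    win <- tr$windows$words
    mov <- vapply(seq_len(5), function(i)
      window_rms_speed(tr$trajectory, win$onset[i], win$offset[i]) >
        config$motion_threshold, logical(1))
    data.frame(participant = tr$participant, condition = tr$condition,
               target = tr$target, word = 1:5,
               yaw_median = med,
               predicted_db = hob,
               moving = mov,
               correct = as.integer(tr$words_correct))
  }))

  ## final-word orientation (word 5 median) per trial
  fin <- word_tab[word_tab$word == 5, ]

  ## (a) per-word orientation summary + optimal-region occupancy
  occ <- lapply(as.character(unique(word_tab$target)), function(tg) {
    reg <- optimal_region(maps[[tg]], margin = 1)
    sub <- word_tab[word_tab$target == as.numeric(tg), ]
    sub$in_region <- (round(wrap_angle(sub$yaw_median)) %% 360) %in%
      (as.numeric(reg) %% 360)
    aggregate(cbind(abs_yaw = abs(sub$yaw_median),
                    in_region = sub$in_region),
              by = list(condition = sub$condition, word = sub$word),
              FUN = mean) |>
      transform(target = as.numeric(tg))
  })
  orientation_summary <- do.call(rbind, occ)

  ## (b) final-word circular summaries + Kuiper tests per target
  circ_rows <- list(); kuiper_rows <- list()
  for (tg in unique(fin$target)) {
    for (cd in intersect(c("AV", "A-only"), conds)) {
      a <- fin$yaw_median[fin$target == tg & fin$condition == cd]
      if (!length(a)) next
      circ_rows[[length(circ_rows) + 1]] <- data.frame(
        target = tg, condition = cd,
        circ_median = circ_median(a),
        median_re_target = re_target_median(a, tg),
        norm_variance = circ_variance(a), n = length(a))
    }
    a <- fin$yaw_median[fin$target == tg & fin$condition == "AV"]
    b <- fin$yaw_median[fin$target == tg & fin$condition == "A-only"]
    if (length(a) >= 5 && length(b) >= 5) {
      kt <- kuiper_two_sample(a, b, n_permutations)
      kuiper_rows[[length(kuiper_rows) + 1]] <- data.frame(
        target = tg, statistic = kt$statistic, p = kt$p_value)
    }
  }
  circ_summary <- if (length(circ_rows)) do.call(rbind, circ_rows) else NULL
  kuiper_summary <- if (length(kuiper_rows)) do.call(rbind, kuiper_rows)
    else NULL

  ## (c) score cells and model predictions in RAU
  cells <- aggregate(cbind(correct = word_tab$correct,
                           predicted_db = word_tab$predicted_db,
                           moving = word_tab$moving),
                     by = list(participant = word_tab$participant,
                               condition = word_tab$condition,
                               target = word_tab$target,
                               word = word_tab$word),
                     FUN = mean)
  ntr <- aggregate(list(n_total = word_tab$correct),
                   by = list(participant = word_tab$participant,
                             condition = word_tab$condition,
                             target = word_tab$target,
                             word = word_tab$word),
                   FUN = length)
  cells$n_total <- ntr$n_total
  cells$n_correct <- round(cells$correct * cells$n_total)
  cells$rau <- rau(cells$n_correct, cells$n_total)

  ## psychometric fit on Static cells
  stat_cells <- cells[cells$condition == "Static", ]
  if (!nrow(stat_cells)) stop("missing cell: no Static condition data")
  fit <- fit_glre(stat_cells)

  cells$pred_prop <- vapply(seq_len(nrow(cells)), function(i)
    predict_score(fit, cells$predicted_db[i],
                  cells$participant[i])$proportion, numeric(1))
  cells$pred_rau <- rau(cells$pred_prop * cells$n_total, cells$n_total)

  ## (e) model-minus-data signed error, moving-word deficit estimate
  mv <- cells$condition != "Static"
  mean_err_rau <- mean(cells$pred_rau[mv] - cells$rau[mv])
  mean_err_db <- rau_error_to_db(mean_err_rau, fit$slope)
  deficit <- deficit_estimate(word_tab, fit, config)

  ## (d) ANOVA tables (lateral targets averaged, in RAU)
  anovas <- build_anovas(cells, conds)

  report <- list(
    orientation_summary = orientation_summary,
    circ_summary = circ_summary, kuiper = kuiper_summary,
    cells = cells, psych_fit = fit, anovas = anovas,
    mean_signed_error_rau = mean_err_rau,
    mean_signed_error_db = mean_err_db,
    dynamic_deficit_db = deficit)
  class(report) <- "rota_report"

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(df, nm) if (!is.null(df))
      write.table(df, file.path(out_dir, nm), sep = "\t", quote = FALSE,
                  row.names = FALSE)
    wt(orientation_summary, "orientation_summary.tsv")
    wt(circ_summary, "circular_summary.tsv")
    wt(kuiper_summary, "kuiper_tests.tsv")
    wt(cells, "score_cells.tsv")
    for (nm in names(anovas))
      write_anova(anovas[[nm]],
                  file.path(out_dir, paste0("anova_", nm, ".tsv")),
                  file.path(out_dir, paste0("anova_", nm, ".json")))
    jsonlite::write_json(
      list(beta0 = fit$beta0, beta1 = fit$beta1, slope = fit$slope,
           ranef = as.list(fit$ranef),
           mean_signed_error_rau = mean_err_rau,
           mean_signed_error_db = mean_err_db,
           dynamic_deficit_db = deficit),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  }
  report
}

## Median final orientation relative to the target, mirroring rear-target
## trials onto one side (left/right symmetric by design).
re_target_median <- function(angles, target) {
  if (target == 0) return(circ_median(angles))
  if (abs(target) == 90) return(wrap_angle(circ_median(angles) - target))
  ## rear: mirror onto the positive side, report the undershoot from 180
  m <- circ_median(abs(wrap_angle(angles)))
  180 - m
}

## Dynamic-deficit estimator: on words spoken in motion, invert the fitted
## psychometric function on pooled observed proportions and compare with
## the pooled predicted dB; continuity-corrected to keep the logit finite.
deficit_estimate <- function(word_tab, fit, config) {
  mv <- word_tab$moving & word_tab$condition != "Static"
  if (!any(mv)) return(NA_real_)
  sub <- word_tab[mv, ]
  g <- aggregate(cbind(correct = sub$correct, predicted_db =
                         sub$predicted_db),
                 by = list(participant = sub$participant,
                           condition = sub$condition, target = sub$target),
                 FUN = mean)
  n <- aggregate(list(n = sub$correct),
                 by = list(participant = sub$participant,
                           condition = sub$condition, target = sub$target),
                 FUN = length)
  g$n <- n$n
  k <- g$correct * g$n
  p_obs <- (k + 0.5) / (g$n + 1)
  u <- fit$ranef[as.character(g$participant)]
  u[is.na(u)] <- 0
  db_obs <- (qlogis(p_obs) - fit$beta0 - u) / fit$beta1
  w <- g$n / sum(g$n)
  sum(w * (g$predicted_db - db_obs))
}

## The ANOVA battery: full three-factor model plus the planned two-factor
## contrasts, all on RAU scores with the lateral targets averaged.
build_anovas <- function(cells, conds) {
  cells$target3 <- ifelse(abs(cells$target) == 90, "lateral",
                          ifelse(cells$target == 0, "front", "rear"))
  avg <- aggregate(list(rau = cells$rau, pred_rau = cells$pred_rau),
                   by = list(participant = cells$participant,
                             condition = cells$condition,
                             target3 = cells$target3, word = cells$word),
                   FUN = mean)
  out <- list()
  if (all(c("Static", "A-only", "AV") %in% conds))
    out$full <- rm_anova(avg, "rau", "participant",
                         c("condition", "target3", "word"))
  contrast <- function(c1, c2, tg) {
    sub <- avg[avg$condition %in% c(c1, c2) & avg$target3 == tg, ]
    rm_anova(sub, "rau", "participant", c("condition", "word"))
  }
  if (all(c("Static", "A-only") %in% conds)) {
    out$lateral_static_vs_aonly <- contrast("Static", "A-only", "lateral")
    out$rear_static_vs_aonly <- contrast("Static", "A-only", "rear")
  }
  if (all(c("AV", "A-only") %in% conds)) {
    out$lateral_av_vs_aonly <- contrast("AV", "A-only", "lateral")
    out$rear_av_vs_aonly <- contrast("AV", "A-only", "rear")
    ## model vs participant data, pooled over AV and A-only
    sub <- avg[avg$condition %in% c("AV", "A-only"), ]
    long <- rbind(
      data.frame(participant = sub$participant, data_type = "participant",
                 rau = sub$rau),
      data.frame(participant = sub$participant, data_type = "model",
                 rau = sub$pred_rau))
    coll <- aggregate(list(rau = long$rau),
                      by = list(participant = long$participant,
                                data_type = long$data_type),
                      FUN = mean)
    out$model_vs_data <- rm_anova(coll, "rau", "participant", "data_type")
  }
  out
}

#' @export
print.rota_report <- function(x, ...) {
  cat("Self-rotation speech analysis report\n")
  print(x$psych_fit)
  cat(sprintf("mean signed model-data error: %.2f RAU (%.2f dB)\n",
              x$mean_signed_error_rau, x$mean_signed_error_db))
  cat(sprintf("dynamic deficit estimate (moving words): %.2f dB\n",
              x$dynamic_deficit_db))
  cat(sprintf("ANOVA tables: %s\n", paste(names(x$anovas), collapse = ", ")))
  invisible(x)
}
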