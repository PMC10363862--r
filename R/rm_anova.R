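## Fully-within-subject repeated-measures ANOVA with Greenhouse-Geisser
## sphericity correction and eta-squared effect sizes.
##
## The sums-of-squares decomposition is the classical one (each within
## effect tested against its effect-by-subject interaction, via aov's
## Error strata); the Greenhouse-Geisser epsilon of each effect is
## computed from the covariance matrix of orthonormal contrast scores of
## the subject-by-cell means, and the corrected p-value uses
## epsilon-scaled degrees of freedom.

#' Repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' @param data data.frame in long format with one observation per subject
#'   and cell of the full factorial (balanced fully-within design).
#' @param dv name of the dependent-variable column (e.g. RAU scores).
#' @param subject name of the subject identifier column.
#' @param factors character vector of within-subject factor column names.
#' @return object of class `rm_anova`: data.frame with one row per effect
#'   (`effect`, `df1`, `df2`, `F`, `epsilon`, `p`, `p_uncorrected`,
#'   `eta_sq`) and attribute `eta_sq_c`, the variance explained by all
#'   listed effects together.
#' @export
rm_anova <- function(data, dv, subject, factors) {
  stopifnot(all(c(dv, subject, factors) %in% names(data)))
  df <- data.frame(
    .y = data[[dv]],
    .s = factor(data[[subject]]),
    lapply(data[factors], factor),
    check.names = FALSE)
  cell <- interaction(df[factors], drop = FALSE)
  counts <- table(df$.s, cell)
  if (any(counts != 1))
    stop("design must be balanced fully-within: exactly one observation ",
         "per subject and cell")

  form <- stats::as.formula(paste(
    ".y ~", paste(factors, collapse = "*"),
    "+ Error(.s/(", paste(factors, collapse = "*"), "))"))
  fit <- stats::aov(form, data = df)
  sm <- summary(fit)

  ss_total <- sum((df$.y - mean(df$.y))^2)
  rows <- list()
  for (stratum in sm) {
    tab <- stratum[[1]]
    effs <- trimws(rownames(tab))
    for (i in seq_along(effs)) {
      if (effs[i] == "Residuals") next
      res <- which(effs == "Residuals")
      eps <- gg_epsilon(df, factors, strsplit(effs[i], ":")[[1]])
      f_val <- tab[i, "F value"]
      df1 <- tab[i, "Df"]; df2 <- tab[res, "Df"]
      rows[[length(rows) + 1]] <- data.frame(
        effect = effs[i], df1 = df1, df2 = df2, F = f_val,
        epsilon = eps,
        p = pf(f_val, eps * df1, eps * df2, lower.tail = FALSE),
        p_uncorrected = tab[i, "Pr(>F)"],
        eta_sq = tab[i, "Sum Sq"] / ss_total)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("rm_anova", "data.frame"),
            eta_sq_c = sum(out$eta_sq), ss_total = ss_total)
}

## Greenhouse-Geisser epsilon for one effect (character vector of factor
## names). Computed from the subject x cell matrix of means over the
## remaining factors, projected on orthonormal interaction contrasts.
gg_epsilon <- function(df, factors, effect_factors) {
  ## subject x cell means, cells ordered with the FIRST effect factor
  ## varying fastest (matches the Kronecker order below)
  subj <- levels(df$.s)
  lev <- lapply(effect_factors, function(f) levels(df[[f]]))
  grid <- expand.grid(lev, KEEP.OUT.ATTRS = FALSE)
  names(grid) <- effect_factors
  p <- nrow(grid)
  if (p == 2) return(1)            # two cells: sphericity trivially holds
  Y <- matrix(NA_real_, length(subj), p)
  key_data <- do.call(paste, c(df[effect_factors], sep = "\r"))
  key_grid <- do.call(paste, c(grid, sep = "\r"))
  for (j in seq_len(p)) {
    sel <- key_data == key_grid[j]
    m <- tapply(df$.y[sel], df$.s[sel], mean)
    Y[, j] <- m[subj]
  }
  ## orthonormal contrasts: kron in reverse factor order so the first
  ## factor's contrast runs along the fastest-varying cell index
  C <- Reduce(`%x%`, rev(lapply(effect_factors, function(f) {
    k <- length(levels(df[[f]]))
    ck <- stats::contr.helmert(k)
    sweep(ck, 2, sqrt(colSums(ck^2)), "/")
  })))
  M <- Y %*% C
  S <- stats::cov(M)
  d <- ncol(M)
  max(1 / d, min(1, sum(diag(S))^2 / (d * sum(S^2))))
}

#' @export
print.rm_anova <- function(x, ...) {
  cat("Repeated-measures ANOVA (Greenhouse-Geisser corrected)\n")
  df <- as.data.frame(x)
  df$F <- round(df$F, 2)
  df$epsilon <- round(df$epsilon, 3)
  df$p <- signif(df$p, 3)
  df$p_uncorrected <- signif(df$p_uncorrected, 3)
  df$eta_sq <- round(df$eta_sq, 4)
  print(df, row.names = FALSE)
  cat(sprintf("cumulative eta^2 (all terms): %.4f\n", attr(x, "eta_sq_c")))
  invisible(x)
}

#' Export an ANOVA table as TSV and/or JSON
#'
#' @param x an [rm_anova()] result.
#' @param path_tsv optional TSV path.
#' @param path_json optional JSON path.
#' @return `x`, invisibly.
#' @export
write_anova <- function(x, path_tsv = NULL, path_json = NULL) {
  df <- as.data.frame(x)
  if (!is.null(path_tsv))
    write.table(df, path_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(path_json))
    jsonlite::write_json(list(effects = df, eta_sq_c = attr(x, "eta_sq_c")),
                         path_json, auto_unbox = TRUE, digits = NA)
  invisible(x)
}
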