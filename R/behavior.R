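#' Sex-by-severity interaction on cluster means
#'
#' Within the autism group, fits
#' `cluster mean ~ sex * score + covariates (+ module dummies)` with
#' listwise deletion of missing scores, and reports the interaction F test
#' together with the within-sex Pearson correlations between score and
#' cluster mean.
#'
#' @param means per-subject cluster means (all subjects; non-ASD and
#'   unscored rows are dropped internally).
#' @param table aligned phenotype table.
#' @param score score column: `ados_css`, `ados_sa` or `ados_rrb`.
#' @param covariates nuisance columns (default age and mFD).
#' @param include_module add ADOS-module dummy covariates (most frequent
#'   module as reference).
#' @param min_per_sex minimum scored subjects per sex.
#' @return list of class `behavior_result`: `score`, `F`, `df1`, `df2`,
#'   `p`, `r_female`, `r_male`, `n`, `covariates`, `include_module`.
#' @export
sex_by_score_glm <- function(means, table, score = "ados_sa",
                             covariates = c("age", "mfd"),
                             include_module = FALSE, min_per_sex = 3L) {
  .assert(score %in% names(table), "score column not found")
  keep <- table$dx == "ASD" & !is.na(table[[score]])
  if (include_module) keep <- keep & !is.na(table$ados_module)
  d <- table[keep, , drop = FALSE]
  y <- means[keep]
  ns <- table(factor(d$sex, levels = c("M", "F")))
  .assert(all(ns >= min_per_sex),
          "single-sex/insufficient scored subjects in a stratum")
  df_fit <- data.frame(y = y, sex = factor(d$sex, levels = c("M", "F")),
                       score = d[[score]])
  for (cv in covariates) df_fit[[cv]] <- d[[cv]]
  rhs <- c("sex * score", covariates)
  if (include_module) {
    mod <- factor(d$ados_module)
    mod <- stats::relevel(mod, ref = names(which.max(table(mod))))
    df_fit$module <- mod
    if (nlevels(droplevels(mod)) > 1L) rhs <- c(rhs, "module")
  }
  fit <- lm(stats::as.formula(paste("y ~", paste(rhs, collapse = " + "))),
            data = df_fit)
  sm <- summary(fit)
  cn <- rownames(sm$coefficients)
  int_row <- grep("^sexF:score$|^score:sexF$", cn)
  .assert(length(int_row) == 1L, "interaction coefficient not found")
  tval <- sm$coefficients[int_row, "t value"]
  df2 <- fit$df.residual
  rF <- suppressWarnings(stats::cor(df_fit$score[df_fit$sex == "F"],
                                    y[df_fit$sex == "F"]))
  rM <- suppressWarnings(stats::cor(df_fit$score[df_fit$sex == "M"],
                                    y[df_fit$sex == "M"]))
  structure(list(score = score, F = tval^2, df1 = 1L, df2 = df2,
                 p = 2 * pt(abs(tval), df2, lower.tail = FALSE),
                 r_female = rF, r_male = rM, n = nrow(d),
                 n_female = ns[["F"]], n_male = ns[["M"]],
                 covariates = covariates, include_module = include_module),
            class = "behavior_result")
}

#' @export
print.behavior_result <- function(x, ...) {
  cat(sprintf(
    "%s sex-by-score interaction: F(%d, %d) = %.3f, p = %.4f (n = %d)\n",
    x$score, x$df1, x$df2, x$F, x$p, x$n))
  cat(sprintf("  within-sex r: female %.3f (n=%d), male %.3f (n=%d)\n",
              x$r_female, x$n_female, x$r_male, x$n_male))
  invisible(x)
}

#' Bonferroni-adjusted alpha
#'
#' @param n_tests number of tests (>= 1).
#' @param alpha family-wise error rate.
#' @return list: `alpha_adjusted` (exact `alpha / n_tests`) and
#'   `alpha_rounded` (two significant digits, as conventionally reported:
#'   0.05/3 prints as 0.017 -> 0.02).
#' @export
bonferroni_alpha <- function(n_tests = 3L, alpha = 0.05) {
  .assert(n_tests >= 1L, "n_tests must be >= 1")
  a <- alpha / n_tests
  list(alpha_adjusted = a, alpha_rounded = signif(a, 1))
}
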