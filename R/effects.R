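#' Per-subject cluster means
#'
#' @param maps `N x V` subject-by-voxel matrix over the full grid.
#' @param cluster_voxels integer voxel indices (or logical mask) of the
#'   cluster.
#' @return numeric vector of length `N`.
#' @export
extract_cluster_means <- function(maps, cluster_voxels) {
  if (is.logical(cluster_voxels)) cluster_voxels <- which(cluster_voxels)
  .assert(length(cluster_voxels) >= 1L, "empty cluster mask")
  rowMeans(as.matrix(maps)[, cluster_voxels, drop = FALSE])
}

## noncentral-F CI for partial eta squared (two-sided, level `level`)
.eta_ci <- function(Fv, df1, df2, level = 0.90) {
  if (!is.finite(Fv) || Fv < 0) return(c(NA_real_, NA_real_))
  if (Fv > 1e8) return(c(1, 1))             # numerically perfect fit
  tail <- (1 - level) / 2
  solve_ncp <- function(target) {
    f <- function(ncp) suppressWarnings(pf(Fv, df1, df2, ncp)) - target
    if (f(0) < 0) return(0)                 # F too small: bound at 0
    hi <- max(Fv * df1 * 4, 10)
    while (f(hi) > 0 && hi < 1e8) hi <- hi * 2
    uniroot(f, c(0, hi), tol = 1e-9)$root
  }
  lo <- solve_ncp(1 - tail)
  hi <- solve_ncp(tail)
  c(lo / (lo + df1 + df2 + 1), hi / (hi + df1 + df2 + 1))
}

#' Full-model effect sizes for cluster means
#'
#' Fits the full regression model (diagnosis, sex, their interaction, age
#' and mean FD) to per-subject cluster means and reports, for each factor
#' term, the partial eta squared from type-III sums of squares,
#' `eta_p^2 = SS_term / (SS_term + SS_error)`, a noncentral-F confidence
#' interval, the covariate-adjusted cell means, and the contrast
#' direction: `dx` is ASD - NT, `sex` is F - M, and the interaction is
#' `(ASD_F - NT_F) - (ASD_M - NT_M)`.
#'
#' @param means per-subject cluster means.
#' @param table phenotype table aligned with `means` (columns `dx`, `sex`
#'   and the covariates).
#' @param covariates nuisance columns of `table` (default age and mFD).
#' @param ci_level confidence level of the eta-squared interval.
#' @param cluster label recorded in the output.
#' @return data frame of class `effect_result` with one row per term
#'   (`dx`, `sex`, `dx_by_sex`): `eta_p_sq`, `ci_lo`, `ci_hi`, `F`,
#'   `df1`, `df2`, `direction`, and adjusted cell means `mean_nt_m`,
#'   `mean_nt_f`, `mean_asd_m`, `mean_asd_f`.
#' @export
full_model_effects <- function(means, table, covariates = c("age", "mfd"),
                               ci_level = 0.90, cluster = 1L) {
  .assert(length(means) == nrow(table), "means must align with table")
  .assert(nlevels(droplevels(table$dx)) == 2L &&
          nlevels(droplevels(table$sex)) == 2L,
          "both factor levels must be present")
  df_fit <- data.frame(y = means, dx = table$dx, sex = table$sex)
  for (cv in covariates) df_fit[[cv]] <- table[[cv]] - mean(table[[cv]])
  fml <- stats::as.formula(paste(
    "y ~ dx * sex", if (length(covariates))
      paste("+", paste(covariates, collapse = " + ")) else ""))
  .assert(nrow(df_fit) > 4L + length(covariates), "too few subjects")
  fit <- lm(fml, data = df_fit,
            contrasts = list(dx = "contr.sum", sex = "contr.sum"))
  ## type-III sums of squares by explicit projection with sum-to-zero
  ## coding: SS_term = ||(P_full - P_reduced) y||^2
  dxs <- ifelse(table$dx == "ASD", 1, -1)
  sxs <- ifelse(table$sex == "F", 1, -1)
  Xf <- cbind(1, dxs, sxs, dxs * sxs)
  for (cv in covariates) Xf <- cbind(Xf, df_fit[[cv]])
  .assert(qr(Xf)$rank == ncol(Xf), "rank-deficient effects design")
  proj <- function(X, y) qr.fitted(qr(X), y)
  yf <- proj(Xf, means)
  ss_err <- sum((means - yf)^2)
  df_err <- nrow(Xf) - ncol(Xf)
  term_col <- c(dx = 2L, sex = 3L, dx_by_sex = 4L)
  ## covariate-adjusted cell means: covariates centered, so cell predictions
  ## at covariate = 0 are the adjusted means
  grid <- expand.grid(dx = levels(table$dx), sex = levels(table$sex))
  for (cv in covariates) grid[[cv]] <- 0
  adj <- stats::predict(fit, newdata = grid)
  names(adj) <- paste(grid$dx, grid$sex, sep = "_")
  dirs <- c(
    dx = mean(adj[c("ASD_M", "ASD_F")]) - mean(adj[c("NT_M", "NT_F")]),
    sex = mean(adj[c("NT_F", "ASD_F")]) - mean(adj[c("NT_M", "ASD_M")]),
    dx_by_sex = (adj[["ASD_F"]] - adj[["NT_F"]]) -
                (adj[["ASD_M"]] - adj[["NT_M"]]))
  out <- do.call(rbind, lapply(names(term_col), function(nm) {
    yr <- proj(Xf[, -term_col[[nm]], drop = FALSE], means)
    ss <- sum((yf - yr)^2)
    df1 <- 1L
    eta <- if (ss + ss_err > 0) ss / (ss + ss_err) else 0
    Fv <- if (ss_err > 0) (ss / df1) / (ss_err / df_err) else Inf
    ci <- if (is.finite(Fv)) .eta_ci(Fv, df1, df_err, ci_level) else c(1, 1)
    data.frame(cluster = cluster, term = nm, eta_p_sq = eta,
               ci_lo = ci[1L], ci_hi = ci[2L], F = Fv, df1 = df1,
               df2 = df_err, direction = sign(dirs[[nm]]),
               mean_nt_m = adj[["NT_M"]], mean_nt_f = adj[["NT_F"]],
               mean_asd_m = adj[["ASD_M"]], mean_asd_f = adj[["ASD_F"]],
               stringsAsFactors = FALSE)
  }))
  class(out) <- c("effect_result", "data.frame")
  out
}

#' Residualize cluster means for visualization
#'
#' OLS residuals of the cluster means against the chosen regressors.  The
#' discovery plots regress out nuisance covariates only (`age`, `mfd`);
#' the full variant also removes the group terms.
#'
#' @param means per-subject values.
#' @param table aligned phenotype table.
#' @param terms regressor columns; `dx`/`sex` enter as 0/1 indicators,
#'   `dx_by_sex` as their product, other names as numeric columns.
#' @return residual vector (orthogonal to every regressor and centered).
#' @export
residualize <- function(means, table,
                        terms = c("age", "mfd")) {
  X <- cbind(intercept = rep(1, nrow(table)))
  for (tm in terms) {
    X <- cbind(X, switch(tm,
      dx = as.integer(table$dx == "ASD"),
      sex = as.integer(table$sex == "F"),
      dx_by_sex = as.integer(table$dx == "ASD") *
                  as.integer(table$sex == "F"),
      table[[tm]]))
  }
  .assert(nrow(X) > ncol(X), "too few observations")
  qrx <- qr(X)
  .assert(qrx$rank == ncol(X), "rank-deficient residualization design")
  as.numeric(qr.resid(qrx, means))
}

#' Robustness/replicability classification
#'
#' A discovery effect is robust/replicable (`R+`) when the replication
#' shows the same contrast direction AND a non-negligible effect size,
#' `eta_p^2 >= threshold` (default 0.01, the small-effect floor);
#' otherwise `R-`.
#'
#' @param discovery,replication `effect_result` rows for the same cluster
#'   and term.
#' @param threshold minimum replication partial eta squared.
#' @return character vector of `"R+"` / `"R-"` per term.
#' @export
classify_replication <- function(discovery, replication, threshold = 0.01) {
  .assert(all(discovery$term == replication$term), "term mismatch")
  ifelse(replication$direction == discovery$direction &
           replication$eta_p_sq >= threshold, "R+", "R-")
}

#' Leave-one-site-out stability of adjusted cell means
#'
#' Refits the full model excluding one site at a time and reports the four
#' covariate-adjusted cell means and the contrast direction of the chosen
#' term, with the fraction of leave-outs that preserve the full-sample
#' direction.
#'
#' @param means per-subject cluster means.
#' @param table aligned phenotype table with a `site` column.
#' @param term one of `dx`, `sex`, `dx_by_sex`.
#' @param covariates nuisance columns.
#' @return list of class `loso_result`: `per_site` data frame (left-out
#'   site, four adjusted means, direction) and `sign_consistency`.
#' @export
loso_stability <- function(means, table, term = "dx_by_sex",
                           covariates = c("age", "mfd")) {
  sites <- unique(as.character(table$site))
  .assert(length(sites) >= 3L, "need at least 3 sites")
  full <- full_model_effects(means, table, covariates)
  full_dir <- full$direction[full$term == term]
  rows <- lapply(sites, function(s) {
    keep <- table$site != s
    ef <- full_model_effects(means[keep], table[keep, , drop = FALSE],
                             covariates)
    r <- ef[ef$term == term, ]
    data.frame(left_out = s, mean_nt_m = r$mean_nt_m,
               mean_nt_f = r$mean_nt_f, mean_asd_m = r$mean_asd_m,
               mean_asd_f = r$mean_asd_f, direction = r$direction,
               stringsAsFactors = FALSE)
  })
  per_site <- do.call(rbind, rows)
  structure(list(per_site = per_site,
                 sign_consistency = mean(per_site$direction == full_dir),
                 full_direction = full_dir, term = term),
            class = "loso_result")
}

#' Overlap of a cluster with cognitive ontology maps
#'
#' Percentage of cluster voxels falling inside each thresholded ontology
#' map.
#'
#' @param cluster_voxels integer indices (or logical mask) of the cluster.
#' @param prob_maps list of numeric vectors over the same grid (e.g. 12
#'   cognitive-component probability maps).
#' @param threshold map threshold (voxels with value strictly above it are
#'   inside; the conventional cut corresponds to P = 1e-5 maps already on
#'   the appropriate scale).
#' @return named numeric vector, one percentage per map.
#' @export
ontology_overlap <- function(cluster_voxels, prob_maps, threshold = 0.5) {
  if (is.logical(cluster_voxels)) cluster_voxels <- which(cluster_voxels)
  .assert(length(cluster_voxels) >= 1L, "empty cluster")
  out <- vapply(prob_maps, function(m) {
    100 * mean(m[cluster_voxels] > threshold)
  }, numeric(1))
  if (is.null(names(out))) names(out) <- paste0("map", seq_along(out))
  out
}

#' Convert an F statistic to partial eta squared
#'
#' Algebraic identity `eta_p^2 = F df1 / (F df1 + df2)`, equivalent to the
#' sums-of-squares definition.
#'
#' @param Fv F statistic.
#' @param df1,df2 numerator and denominator degrees of freedom.
#' @return partial eta squared.
#' @export
f_to_eta_sq <- function(Fv, df1, df2) {
  Fv * df1 / (Fv * df1 + df2)
}
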