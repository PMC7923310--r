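#' Generate a multi-site phenotype table
#'
#' Draws one record per subject for a two-by-two diagnosis-by-sex design
#' with the exact per-site cell counts requested in the specification.
#' Ages are uniform within the spec range; full-scale IQ is normal with the
#' group-specific mean; the target mean framewise displacement is drawn on
#' the log scale around the group mean plus the site's motion offset and
#' clipped to a plausible range.
#'
#' @param spec a [cohort_spec()].
#' @param sites a [site_spec()] with at least `spec$n_sites` rows.
#' @return a `data.frame` with columns `subject_id`, `site`, `dx`
#'   (factor NT/ASD), `sex` (factor M/F), `age`, `fiq`, `mfd` (target mean
#'   FD, mm), and empty ADOS columns (`ados_css`, `ados_sa`, `ados_rrb`,
#'   `ados_module`, `NA` until [generate_behavior()] fills the ASD rows).
#' @export
generate_phenotypes <- function(spec, sites = site_spec()) {
  .assert(inherits(spec, "cohort_spec"), "spec must be a cohort_spec")
  .assert(nrow(sites) >= spec$n_sites, "site_spec has too few sites")
  set.seed(spec$rng_seed)
  cells <- expand.grid(dx = c("NT", "ASD"), sex = c("M", "F"),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows <- vector("list", 0L)
  for (s in seq_len(spec$n_sites)) {
    for (ci in seq_len(4L)) {
      dx <- cells$dx[c(1, 3, 2, 4)[ci]]   # order NT_M, NT_F, ASD_M, ASD_F
      sex <- cells$sex[c(1, 3, 2, 4)[ci]]
      key <- paste(dx, sex, sep = "_")
      n <- spec$cell_sizes[s, key]
      if (n == 0L) next
      age <- runif(n, spec$age_range[1L], spec$age_range[2L])
      fiq <- rnorm(n, spec$fiq_mean_by_group[[dx]], spec$fiq_sd)
      mfd <- exp(rnorm(n, log(spec$mfd_mean_by_group[[dx]] +
                              sites$motion_shift[s]), 0.35))
      mfd <- pmin(pmax(mfd, 0.02), 0.35)
      rows[[length(rows) + 1L]] <- data.frame(
        site = sites$site[s], dx = dx, sex = sex, age = age, fiq = fiq,
        mfd = mfd, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  tab <- data.frame(subject_id = sprintf("sub%04d", seq_len(nrow(tab))), tab,
                    stringsAsFactors = FALSE)
  tab$dx <- factor(tab$dx, levels = c("NT", "ASD"))
  tab$sex <- factor(tab$sex, levels = c("M", "F"))
  tab$ados_css <- NA_real_
  tab$ados_sa <- NA_real_
  tab$ados_rrb <- NA_real_
  tab$ados_module <- NA_integer_
  tab
}

#' Generate a realistic 6-parameter motion trace
#'
#' A bounded random walk over `T` timepoints in three translations (mm) and
#' three rotations (rad), with step sizes calibrated so that the realized
#' mean framewise displacement (Power convention, 50 mm head radius)
#' matches the subject's target within sampling error.
#'
#' @param n_timepoints number of volumes (>= 2).
#' @param target_mfd target mean framewise displacement in mm; 0 gives a
#'   constant trace.
#' @param bound reflection bound on each parameter (mm or rad).
#' @param radius head radius (mm) used in the FD calibration.
#' @return a `T x 6` numeric matrix with columns
#'   `trans_x, trans_y, trans_z, rot_x, rot_y, rot_z`.
#' @export
generate_motion <- function(n_timepoints, target_mfd, bound = 3,
                            radius = 50) {
  .assert(n_timepoints >= 2L, "need at least 2 timepoints")
  .assert(is.finite(target_mfd) && target_mfd >= 0, "invalid target mFD")
  p <- matrix(0, n_timepoints, 6L,
              dimnames = list(NULL, c("trans_x", "trans_y", "trans_z",
                                      "rot_x", "rot_y", "rot_z")))
  if (target_mfd > 0) {
    ## E|N(0, s^2)| = s * sqrt(2/pi); split FD half translation, half rotation
    s_t <- (target_mfd / 2) / (3 * sqrt(2 / pi))
    s_r <- (target_mfd / 2) / (radius * 3 * sqrt(2 / pi))
    steps <- cbind(matrix(rnorm(3L * (n_timepoints - 1L), 0, s_t), ncol = 3L),
                   matrix(rnorm(3L * (n_timepoints - 1L), 0, s_r), ncol = 3L))
    p[-1L, ] <- apply(steps, 2L, cumsum)
    ## reflect at +/- bound (rarely triggered at realistic step sizes)
    over <- abs(p) > bound
    p[over] <- sign(p[over]) * (2 * bound - abs(p[over]))
  }
  p
}

#' Fill symptom-severity scores for the autism rows
#'
#' Generates ADOS calibrated severity scores (total CSS, social affect,
#' repetitive behavior) for ASD subjects only, such that the within-sex
#' Pearson correlation between the social-affect score and a supplied
#' region signal matches the behavior spec targets up to rounding and
#' range clipping.  Neurotypical rows keep missing scores.
#'
#' @param table phenotype table from [generate_phenotypes()].
#' @param roi_signal numeric vector, one value per row of `table` (e.g. a
#'   cluster-mean metric value); only ASD rows are used.
#' @param spec a [behavior_spec()].
#' @return `table` with ADOS columns filled for ASD rows.
#' @export
generate_behavior <- function(table, roi_signal, spec = behavior_spec()) {
  .assert(inherits(spec, "behavior_spec"), "spec must be a behavior_spec")
  .assert(length(roi_signal) == nrow(table),
          "roi_signal must have one value per row")
  asd <- table$dx == "ASD"
  .assert(any(asd), "no ASD rows to score")
  for (cl in c("ados_css", "ados_sa", "ados_rrb")) {
    if (is.null(table[[cl]])) table[[cl]] <- NA_real_
  }
  if (is.null(table$ados_module)) table$ados_module <- NA_integer_
  lo <- spec$score_range[1L]; hi <- spec$score_range[2L]
  mid <- (lo + hi) / 2; spread <- (hi - lo) / 4
  for (sx in c("M", "F")) {
    idx <- which(asd & table$sex == sx)
    if (!length(idx)) {
      .assert(FALSE, sprintf("target correlation given for empty %s stratum", sx))
    }
    r <- if (sx == "F") spec$r_female else spec$r_male
    z <- as.numeric(scale(roi_signal[idx]))
    if (any(!is.finite(z))) z <- rep(0, length(idx))
    lat <- r * z + sqrt(1 - r^2) * rnorm(length(idx))
    sa <- pmin(pmax(round(mid + spread * lat), lo), hi)
    rrb <- pmin(pmax(round(mid + spread * rnorm(length(idx))), lo), hi)
    css <- pmin(pmax(round((2 * sa + rrb) / 3 +
                           0.5 * rnorm(length(idx))), lo), hi)
    table$ados_sa[idx] <- sa
    table$ados_rrb[idx] <- rrb
    table$ados_css[idx] <- css
    table$ados_module[idx] <- as.integer(sample(
      names(spec$module_probs), length(idx), replace = TRUE,
      prob = spec$module_probs))
  }
  table
}
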