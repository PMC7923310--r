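#' Default posterior-midline seed region
#'
#' A small posterior cingulate-like box straddling the x mid-plane, used
#' as the default seed of the seed-connectivity metric on synthetic grids.
#'
#' @param dims grid dimensions.
#' @return integer voxel indices.
#' @export
default_pcc_seed <- function(dims = c(24L, 24L, 16L)) {
  roi_box(dims, x = c(dims[1L] / 2L - 1L, dims[1L] / 2L + 2L),
          y = c(round(dims[2L] * 0.3), round(dims[2L] * 0.3) + 2L),
          z = c(round(dims[3L] * 0.55), round(dims[3L] * 0.55) + 2L))
}

#' Compute metric maps for one denoised subject
#'
#' @param den output of [denoise_subject()].
#' @param metrics character subset of
#'   `c("vmhc", "pcc_ifc", "reho", "dc", "falff")`.
#' @param seed_voxels seed region for `pcc_ifc`.
#' @param smooth_fwhm FWHM (mm) of the metric-map smoothing (0 = none);
#'   smoothing is applied to the derivative maps, not the series.
#' @param standardize z-score the amplitude metrics within the mask.
#' @return named list of [metric_map()] objects.
#' @export
subject_metric_maps <- function(den, metrics = "vmhc",
                                seed_voxels = NULL, smooth_fwhm = 6,
                                standardize = TRUE) {
  f <- den$filtered
  out <- list()
  for (m in metrics) {
    mp <- switch(m,
      vmhc = vmhc(f),
      pcc_ifc = seed_ifc(f, seed_voxels %||% default_pcc_seed(f$dims)),
      reho = reho(f),
      dc = degree_centrality(f),
      falff = falff(den$unfiltered),
      stop("unknown metric: ", m))
    if (standardize && mp$standardization == "raw") mp <- standardize_map(mp)
    if (smooth_fwhm > 0) {
      mp$values <- smooth_gaussian(mp$values, smooth_fwhm, f$voxel_size,
                                   dims = f$dims, mask = mp$mask)
    }
    out[[m]] <- mp
  }
  out
}

#' Simulate and analyze one synthetic multi-site study
#'
#' End-to-end pipeline on a synthetic cohort: phenotype generation, motion
#' simulation with realized mean FD, per-subject BOLD generation with
#' ground-truth effects and site batch structure, nuisance denoising
#' (24-parameter motion model + CompCor + trends, band-pass), metric
#' computation and smoothing, eligibility and site-cell QC, ComBat site
#' harmonization protecting the group design, voxel-wise GLM for
#' diagnosis, sex and their interaction, GRF cluster correction, and
#' effect sizes for every significant cluster.
#'
#' @param spec a [cohort_spec()].
#' @param sites a [site_spec()].
#' @param effects an [effect_spec()] (default [default_effects()]).
#' @param behavior optional [behavior_spec()]; when supplied, symptom
#'   scores are generated from the first effect region's signal and the
#'   sex-by-severity model is fitted on it.
#' @param seed integer seed controlling every random draw.
#' @param metrics metric maps to compute (default `"vmhc"`, the carrier of
#'   the fixture's ground-truth effects).
#' @param z_thresh voxel cluster-forming threshold (default 3.1).
#' @param cluster_alpha cluster-level significance (default 0.01, i.e.
#'   0.05 Bonferroni-shared across the five metrics).
#' @param smooth_fwhm metric-map smoothing FWHM in mm.
#' @param gsr use the global-signal pipeline variant.
#' @param include_fiq add FIQ to the group design.
#' @param qc apply eligibility and site-cell filters before analysis.
#' @return object of class `study_result`: `pheno` (analyzed subjects),
#'   `metric_mats` (named list of `N x V` harmonized matrices),
#'   `glm` (per metric), `smoothness`, `clusters` (per metric x term with
#'   `p_grf`), `effects` (effect sizes of significant clusters),
#'   `behavior`, `mask`, `dims`, plus the generating specs.
#' @export
run_study <- function(spec, sites = site_spec(),
                      effects = default_effects(spec$grid_dims),
                      behavior = NULL, seed = 1L, metrics = "vmhc",
                      z_thresh = 3.1, cluster_alpha = 0.01,
                      smooth_fwhm = 6, gsr = FALSE, include_fiq = FALSE,
                      qc = TRUE) {
  spec$rng_seed <- as.integer(seed)
  pheno <- generate_phenotypes(spec, sites)
  n <- nrow(pheno)
  dims <- spec$grid_dims
  mask <- ellipsoid_mask(dims)
  V <- prod(dims)
  site_idx <- match(pheno$site, sites$site)

  mats <- lapply(metrics, function(m) matrix(0, n, V))
  names(mats) <- metrics
  mfd_real <- numeric(n)
  for (i in seq_len(n)) {
    set.seed(seed + 1000L + i)
    mot <- generate_motion(spec$n_timepoints, pheno$mfd[i])
    mfd_real[i] <- mean(framewise_displacement(mot))
    bold <- generate_bold(pheno[i, ], spec, effects,
                          site = sites[site_idx[i], ], motion = mot,
                          mask = mask)
    den <- denoise_subject(bold, motion = mot, gsr = gsr)
    mm <- subject_metric_maps(den, metrics, smooth_fwhm = smooth_fwhm)
    for (m in metrics) mats[[m]][i, ] <- mm[[m]]$values
  }
  pheno$mfd <- mfd_real

  keep <- rep(TRUE, n)
  qc_info <- NULL
  if (qc) {
    elig <- eligibility_filter(pheno)
    keep <- pheno$subject_id %in% elig$retained
    scf <- site_cell_filter(pheno[keep, , drop = FALSE])
    keep <- keep & pheno$subject_id %in% scf$table$subject_id
    qc_info <- list(eligibility = elig, dropped_sites = scf$dropped_sites)
  }
  pheno <- pheno[keep, , drop = FALSE]
  mats <- lapply(mats, function(m) m[keep, , drop = FALSE])

  design <- build_design(pheno, include_fiq = include_fiq)
  protect <- design[, setdiff(colnames(design), "intercept"), drop = FALSE]
  glms <- list(); smooths <- list(); clus <- list(); effs <- list()
  for (m in metrics) {
    dat <- mats[[m]]
    harm <- combat_apply(dat[, mask, drop = FALSE],
                         fit <- combat_fit(dat[, mask, drop = FALSE],
                                           pheno$site, protect))
    dat[, mask] <- harm
    mats[[m]] <- dat
    g <- voxelwise_glm(dat[, mask, drop = FALSE], design)
    res_full <- matrix(0, nrow(dat), V)
    res_full[, mask] <- g$residuals
    sm <- estimate_smoothness(res_full, mask, dims, spec$voxel_size)
    glms[[m]] <- g
    smooths[[m]] <- sm
    for (term in names(g$z)) {
      zfull <- numeric(V)
      zfull[mask] <- g$z[[term]]
      cl <- grf_correct(extract_clusters(zfull, dims, mask, z_thresh),
                        z_thresh, sm)
      if (nrow(cl)) {
        cl$metric <- m; cl$term <- term
        clus[[paste(m, term)]] <- cl
        sig <- which(cl$p_grf < cluster_alpha)
        for (s in sig) {
          mn <- extract_cluster_means(dat, cl$voxels[[s]])
          ef <- full_model_effects(mn, pheno,
                                   cluster = paste(m, term, cl$label[s]))
          ef$metric <- m; ef$map_term <- term
          effs[[paste(m, term, s)]] <- ef
        }
      }
    }
  }
  clusters <- if (length(clus)) do.call(rbind, clus) else NULL
  eff_tab <- if (length(effs)) do.call(rbind, effs) else NULL

  behav <- NULL
  if (!is.null(behavior) && length(effects$effects)) {
    set.seed(seed + 777L)
    roi1 <- effects$effects[[1L]]$roi
    sig_means <- extract_cluster_means(mats[[metrics[1L]]], roi1)
    pheno <- generate_behavior(pheno, sig_means, behavior)
    behav <- sex_by_score_glm(sig_means, pheno, "ados_sa")
  }

  structure(list(pheno = pheno, metric_mats = mats, glm = glms,
                 smoothness = smooths, clusters = clusters,
                 effects = eff_tab, behavior = behav, mask = mask,
                 dims = dims, spec = spec, sites = sites,
                 effect_spec = effects, design = design,
                 qc = qc_info, seed = seed),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat("Synthetic study:", nrow(x$pheno), "subjects analyzed,",
      length(x$metric_mats), "metric(s)\n")
  if (!is.null(x$clusters)) {
    cat("Clusters (voxel |Z| >", "3.1):\n")
    print(x$clusters[, c("metric", "term", "size", "peak_z", "sign",
                         "p_grf")], row.names = FALSE, digits = 3)
  } else cat("No suprathreshold clusters.\n")
  invisible(x)
}

#' Detection check against a ground-truth region
#'
#' Whether any significant cluster of the given metric/term overlaps at
#' least `min_overlap` of the true region.
#'
#' @param study a [run_study()] result.
#' @param roi ground-truth voxel indices.
#' @param metric,term which map to inspect.
#' @param cluster_alpha cluster significance level.
#' @param min_overlap minimum fraction of `roi` covered.
#' @return list: `detected`, `overlap` (best fraction), `cluster` row or
#'   `NULL`.
#' @export
roi_detection <- function(study, roi, metric = "vmhc",
                          term = "dx_by_sex", cluster_alpha = 0.01,
                          min_overlap = 0.5) {
  cl <- study$clusters
  if (is.null(cl)) return(list(detected = FALSE, overlap = 0, cluster = NULL))
  cl <- cl[cl$metric == metric & cl$term == term &
           cl$p_grf < cluster_alpha, , drop = FALSE]
  if (!nrow(cl)) return(list(detected = FALSE, overlap = 0, cluster = NULL))
  ## a bilateral ground-truth region is recovered as two mirror clusters,
  ## so overlap is judged on the union of significant clusters
  ov_union <- length(intersect(unique(unlist(cl$voxels)), roi)) / length(roi)
  ov <- vapply(cl$voxels, function(v) {
    length(intersect(v, roi)) / length(roi)
  }, numeric(1))
  best <- which.max(ov)
  list(detected = ov_union >= min_overlap, overlap = ov_union,
       cluster = cl[best, , drop = FALSE])
}
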