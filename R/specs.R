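#' Cohort specification
#'
#' Describes a multi-site two-by-two (diagnosis by sex) cohort and the
#' acquisition grid of its synthetic BOLD volumes.  The default values give
#' the desk-scale study fixture: 4 sites with 10 subjects per
#' diagnosis-by-sex cell (N = 160), a 24 x 24 x 16 grid at 3 mm, 150
#' timepoints at TR = 2 s, ages 7-18 years, full-scale IQ means of 106
#' (autism) and 112 (neurotypical) with SD 13.
#'
#' @param n_sites number of acquisition sites.
#' @param cell_sizes per-site counts for the four cells, an `n_sites` x 4
#'   matrix (columns NT-M, NT-F, ASD-M, ASD-F) or a length-4 vector recycled
#'   across sites.
#' @param age_range inclusive age range in years, drawn uniformly.
#' @param fiq_mean_by_group named length-2 vector of full-scale IQ means for
#'   `NT` and `ASD`.
#' @param fiq_sd common IQ standard deviation.
#' @param grid_dims voxel grid `c(nx, ny, nz)`; `nx` must be even so every
#'   voxel has an exact left-right mirror.
#' @param voxel_size isotropic voxel edge in mm.
#' @param n_timepoints number of volumes.
#' @param tr repetition time in seconds.
#' @param mfd_mean_by_group named length-2 vector of target mean framewise
#'   displacement (mm) for `NT` and `ASD` subjects.
#' @param rng_seed integer seed making every downstream draw reproducible.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_sites = 4L,
                        cell_sizes = c(10L, 10L, 10L, 10L),
                        age_range = c(7, 18),
                        fiq_mean_by_group = c(NT = 112, ASD = 106),
                        fiq_sd = 13,
                        grid_dims = c(24L, 24L, 16L),
                        voxel_size = 3,
                        n_timepoints = 150L,
                        tr = 2,
                        mfd_mean_by_group = c(NT = 0.09, ASD = 0.12),
                        rng_seed = 20260101L) {
  if (is.null(dim(cell_sizes))) {
    .assert(length(cell_sizes) == 4L, "cell_sizes must have 4 columns")
    cell_sizes <- matrix(rep(as.integer(cell_sizes), each = n_sites),
                         nrow = n_sites)
  }
  cell_sizes <- as.matrix(cell_sizes)
  colnames(cell_sizes) <- c("NT_M", "NT_F", "ASD_M", "ASD_F")
  .assert(nrow(cell_sizes) == n_sites, "cell_sizes rows must equal n_sites")
  .assert(all(cell_sizes >= 0), "all cell counts must be >= 0")
  .assert(grid_dims[1L] %% 2L == 0L, "nx must be even (mirror pairs)")
  .assert(tr > 0, "tr must be > 0")
  .assert(length(age_range) == 2L && age_range[1L] < age_range[2L] &&
          age_range[1L] > 0 && age_range[2L] < 100,
          "age_range must be increasing and within (0, 100)")
  .assert(all(c("NT", "ASD") %in% names(fiq_mean_by_group)),
          "fiq_mean_by_group needs NT and ASD entries")
  .assert(n_timepoints >= 2L, "n_timepoints must be >= 2")
  structure(
    list(n_sites = as.integer(n_sites), cell_sizes = cell_sizes,
         age_range = as.numeric(age_range),
         fiq_mean_by_group = fiq_mean_by_group, fiq_sd = fiq_sd,
         grid_dims = as.integer(grid_dims), voxel_size = voxel_size,
         n_timepoints = as.integer(n_timepoints), tr = tr,
         mfd_mean_by_group = mfd_mean_by_group,
         rng_seed = as.integer(rng_seed)),
    class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Cohort specification\n")
  cat("  sites:", x$n_sites, " N =", sum(x$cell_sizes), "\n")
  cat("  grid:", paste(x$grid_dims, collapse = " x "),
      "voxels @", x$voxel_size, "mm;", x$n_timepoints,
      "timepoints @ TR =", x$tr, "s\n")
  cat("  age:", paste(x$age_range, collapse = "-"), "y; FIQ NT",
      x$fiq_mean_by_group[["NT"]], "/ ASD",
      x$fiq_mean_by_group[["ASD"]], "(SD", x$fiq_sd, ")\n")
  invisible(x)
}

#' Site batch-effect specification
#'
#' Per-site location/scale batch parameters of the ComBat model.  `gamma`
#' (additive, metric units) and `delta` (multiplicative, > 0) act on the
#' link scale of the generative coupling parameters (Fisher z for
#' correlation-type couplings, logit for variance fractions) so that the
#' resulting metric maps carry an additive/multiplicative site structure;
#' `motion_shift` offsets the site's target mean framewise displacement.
#'
#' @param gamma numeric vector, one additive offset per site.
#' @param delta numeric vector of positive scale factors per site.
#' @param motion_shift numeric vector, per-site mean-FD offset in mm.
#' @return an object of class `site_spec` (data frame, one row per site).
#' @export
site_spec <- function(gamma = c(0.3, -0.3, 0.15, -0.15),
                      delta = c(1.2, 0.8, 1.1, 0.9),
                      motion_shift = c(0.01, -0.01, 0.02, 0)) {
  n <- max(length(gamma), length(delta), length(motion_shift))
  gamma <- rep_len(gamma, n); delta <- rep_len(delta, n)
  motion_shift <- rep_len(motion_shift, n)
  .assert(all(delta > 0), "delta must be > 0")
  structure(data.frame(site = paste0("site", seq_len(n)), gamma = gamma,
                       delta = delta, motion_shift = motion_shift),
            class = c("site_spec", "data.frame"))
}

#' Ground-truth effect specification
#'
#' A list of injected group effects, each tied to one generative signal
#' channel of the synthetic BOLD model.  Inside its target region the
#' channel's coupling (or variance-fraction) parameter equals
#' `base + beta_dx * dx + beta_sex * sex + beta_int * dx * sex` with
#' `dx, sex` coded 0/1 (ASD = 1, female = 1).
#'
#' @param effects list of effects; each a list with fields `channel` (one of
#'   `"vmhc"`, `"reho"`, `"pcc_ifc"`, `"dc"`, `"falff"`), `roi` (integer
#'   voxel indices), `base`, `beta_dx`, `beta_sex`, `beta_int`, and for the
#'   `pcc_ifc` channel an additional `seed` voxel set.
#' @param base_coupling baseline homotopic coupling (correlation between
#'   mirror-pair voxels) applied brain-wide outside `vmhc` target regions.
#' @return object of class `effect_spec`.
#' @export
effect_spec <- function(effects = list(), base_coupling = 0.3) {
  .assert(base_coupling >= 0 && base_coupling <= 1,
          "base_coupling must be in [0, 1]")
  for (e in effects) {
    .assert(e$channel %in% c("vmhc", "reho", "pcc_ifc", "dc", "falff"),
            "unknown effect channel")
    .assert(length(e$roi) >= 1L, "effect ROI is empty")
    pars <- e$base + c(0, e$beta_dx, e$beta_sex,
                       e$beta_dx + e$beta_sex + e$beta_int)
    ## 1 is allowed as the noise-free limit (pure shared signal)
    .assert(all(pars >= 0 & pars <= 1),
            "coupling/fraction parameters must stay in [0, 1] in every cell")
  }
  structure(list(effects = effects, base_coupling = base_coupling),
            class = "effect_spec")
}

#' Default ground-truth effects of the study fixture
#'
#' Two homotopic-coupling effects mimicking the qualitative discovery
#' pattern: a negative diagnosis-by-sex interaction on a bilateral
#' dorsolateral-occipital-like region (females with autism lose homotopic
#' coupling) and diagnosis plus sex main effects on a posterior midline
#' region.
#'
#' In the lateral region the four cell couplings are NT-M 0.30, NT-F 0.36,
#' ASD-M 0.30, ASD-F 0.08: neurotypical females highest, females with
#' autism lowest, the qualitative discovery ordering.
#'
#' @param dims grid dimensions (defaults to the fixture grid).
#' @param beta_int lateral interaction magnitude on the coupling scale
#'   (negative).
#' @param lat_beta_sex small positive sex effect in the lateral region
#'   that puts neurotypical females on top.
#' @param beta_dx,beta_sex midline main-effect magnitudes.
#' @return an `effect_spec`.
#' @export
default_effects <- function(dims = c(24L, 24L, 16L), beta_int = -0.28,
                            lat_beta_sex = 0.06,
                            beta_dx = -0.15, beta_sex = -0.10) {
  ## boxes in fractional grid coordinates so any grid stays inside the mask
  fr <- function(f, d) pmax(1L, pmin(d, round(f * d)))
  zc <- c(fr(0.45, dims[3L]), fr(0.65, dims[3L]))
  lat_l <- roi_box(dims, x = c(fr(0.18, dims[1L]), fr(0.27, dims[1L])),
                   y = c(fr(0.38, dims[2L]), fr(0.52, dims[2L])), z = zc)
  lat <- sort(c(lat_l, mirror_voxels(lat_l, dims)))
  mid <- roi_box(dims, x = c(dims[1L] / 2L - 1L, dims[1L] / 2L + 2L),
                 y = c(fr(0.6, dims[2L]), fr(0.72, dims[2L])), z = zc)
  effect_spec(list(
    list(channel = "vmhc", roi = lat, base = 0.3, beta_dx = 0,
         beta_sex = lat_beta_sex, beta_int = beta_int,
         label = "lat_occipital"),
    list(channel = "vmhc", roi = mid, base = 0.3, beta_dx = beta_dx,
         beta_sex = beta_sex, beta_int = 0, label = "midline")
  ))
}

#' Brain-behavior coupling specification
#'
#' Targets for the sex-differential association between a cluster-level
#' signal and autism symptom severity (ADOS calibrated severity scores).
#' Defaults follow the discovery pattern: social-affect severity correlates
#' negatively with the region signal in females (`r_female = -0.29`) but
#' not males (`r_male = 0.03`).
#'
#' @param r_female,r_male target within-sex Pearson correlations between the
#'   region signal and the social-affect severity score, `|r| < 1`.
#' @param score_range inclusive integer bounds of the calibrated severity
#'   scores (CSS total, social affect, repetitive behavior).
#' @param module_probs named probabilities of ADOS modules 2-4.
#' @return object of class `behavior_spec`.
#' @export
behavior_spec <- function(r_female = -0.29, r_male = 0.03,
                          score_range = c(1L, 10L),
                          module_probs = c("2" = 0.2, "3" = 0.4, "4" = 0.4)) {
  .assert(abs(r_female) < 1 && abs(r_male) < 1, "|r| must be < 1")
  .assert(score_range[1L] < score_range[2L], "invalid score_range")
  .assert(abs(sum(module_probs) - 1) < 1e-8, "module_probs must sum to 1")
  structure(list(r_female = r_female, r_male = r_male,
                 score_range = as.integer(score_range),
                 module_probs = module_probs),
            class = "behavior_spec")
}

#' Read or write a cohort specification as JSON or YAML
#'
#' @param spec a `cohort_spec`.
#' @param path file path ending in `.json`, `.yaml` or `.yml`.
#' @return `write_cohort_spec` returns `path` invisibly;
#'   `read_cohort_spec` returns a `cohort_spec`.
#' @export
write_cohort_spec <- function(spec, path) {
  x <- unclass(spec)
  cs <- x$cell_sizes
  x$cell_sizes <- lapply(seq_len(nrow(cs)), function(i) unname(cs[i, ]))
  ## named vectors must become objects, not bare arrays
  x$fiq_mean_by_group <- as.list(x$fiq_mean_by_group)
  x$mfd_mean_by_group <- as.list(x$mfd_mean_by_group)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' @rdname write_cohort_spec
#' @export
read_cohort_spec <- function(path) {
  x <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  cs <- x$cell_sizes
  if (is.list(cs)) cs <- do.call(rbind, lapply(cs, unlist))
  if (is.null(dim(cs))) cs <- matrix(cs, nrow = x$n_sites)
  cohort_spec(n_sites = x$n_sites, cell_sizes = cs,
              age_range = unlist(x$age_range),
              fiq_mean_by_group = unlist(x$fiq_mean_by_group),
              fiq_sd = x$fiq_sd, grid_dims = unlist(x$grid_dims),
              voxel_size = x$voxel_size, n_timepoints = x$n_timepoints,
              tr = x$tr, mfd_mean_by_group = unlist(x$mfd_mean_by_group),
              rng_seed = x$rng_seed)
}
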