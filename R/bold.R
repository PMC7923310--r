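#' BOLD image container
#'
#' Internally a `T x V` matrix over the full grid (column-major voxel
#' order) plus grid geometry; convertible to/from a 4D array for NIfTI IO.
#'
#' @param data `T x V` numeric matrix (or 4D array `nx x ny x nz x T`).
#' @param dims grid dimensions `c(nx, ny, nz)`.
#' @param voxel_size isotropic voxel edge, mm.
#' @param tr repetition time, seconds.
#' @param mask logical vector of length `prod(dims)` (default: all TRUE).
#' @return object of class `bold_image`.
#' @export
bold_image <- function(data, dims, voxel_size, tr, mask = NULL) {
  if (length(dim(data)) == 4L) {
    dims <- dim(data)[1:3]
    data <- t(matrix(data, prod(dims), dim(data)[4L]))
  }
  .assert(ncol(data) == prod(dims), "data columns must match grid size")
  .assert(tr > 0, "tr must be > 0")
  mask <- mask %||% rep(TRUE, prod(dims))
  structure(list(data = data, dims = as.integer(dims),
                 voxel_size = voxel_size, tr = tr, mask = mask),
            class = "bold_image")
}

#' @export
print.bold_image <- function(x, ...) {
  cat("BOLD image:", paste(x$dims, collapse = " x "), "voxels @",
      x$voxel_size, "mm,", nrow(x$data), "timepoints @ TR =", x$tr,
      "s,", sum(x$mask), "in mask\n")
  invisible(x)
}

#' Convert a bold_image to a 4D array
#' @param bold a `bold_image`.
#' @return `nx x ny x nz x T` array.
#' @export
as_bold_array <- function(bold) {
  array(t(bold$data), c(bold$dims, nrow(bold$data)))
}

## stationary AR(1) series with unit marginal variance, column-wise
.ar1_noise <- function(n_timepoints, n_series, phi) {
  x <- matrix(rnorm(n_timepoints * n_series), n_timepoints, n_series)
  if (phi != 0) {
    for (t in 2:n_timepoints) x[t, ] <- phi * x[t - 1L, ] + x[t, ]
    x <- x * sqrt(1 - phi^2)
  }
  x
}

## band-limited unit-variance noise (for the fALFF ground-truth channel)
.inband_noise <- function(n_timepoints, n_series, tr, band = c(0.01, 0.1)) {
  x <- matrix(rnorm(n_timepoints * n_series), n_timepoints, n_series)
  x <- .fft_bandpass(x, tr, band[1L], band[2L])
  sds <- sqrt(colMeans(x^2))
  sds[sds == 0] <- 1
  sweep(x, 2L, sds, "/")
}

#' Generate one subject's synthetic 4D BOLD volume
#'
#' Low-rank latent-signal model with AR(1) voxel noise.  Mirror-pair voxels
#' share a latent signal with mixing weight equal to the square root of the
#' subject's homotopic coupling, so the pairwise correlation equals the
#' coupling parameter; additional latent channels give independently
#' tunable ground truth for regional homogeneity, seed connectivity, degree
#' centrality and the in-band variance fraction.  Inside each effect's
#' target region the channel parameter is
#' `base + beta_dx*dx + beta_sex*sex + beta_int*dx*sex`.  Site batch
#' parameters act on the link scale (Fisher z for couplings, logit for
#' fractions): `link(par) -> delta * link(par) + gamma`.  A motion-locked
#' nuisance component (a linear combination of the realized motion
#' parameters and their backward differences, hence exactly removable by
#' the 24-parameter motion model) is mixed into every voxel.
#'
#' @param subject one-row data frame with `dx` and `sex` (factors NT/ASD,
#'   M/F).
#' @param spec a [cohort_spec()].
#' @param effects an [effect_spec()].
#' @param site one row of a [site_spec()] (`NULL` for no site effect).
#' @param motion optional `T x 6` motion trace from [generate_motion()];
#'   its standardized parameter combination is the nuisance regressor.
#' @param mask brain mask (default [ellipsoid_mask()] of the grid).
#' @param phi AR(1) coefficient shared by latents and voxel noise, so that
#'   band-pass filtering preserves the generative correlations.
#' @param motion_weight mixing weight of the motion nuisance component.
#' @param seed optional integer making the draw reproducible.
#' @return a [bold_image()] with attributes `coupling` (the per-voxel
#'   realized homotopic coupling) recorded for ground-truth checks.
#' @export
generate_bold <- function(subject, spec, effects = effect_spec(),
                          site = NULL, motion = NULL, mask = NULL,
                          phi = 0.3, motion_weight = 0.2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dims <- spec$grid_dims
  V <- prod(dims); Tt <- spec$n_timepoints
  mask <- mask %||% ellipsoid_mask(dims)
  dx <- as.integer(subject$dx == "ASD")
  sx <- as.integer(subject$sex == "F")

  ## --- per-voxel channel parameters -------------------------------------
  coupling <- ifelse(mask, effects$base_coupling, 0)
  frac_inband <- numeric(V)                       # fALFF channel
  chan_w2 <- NULL                                 # latent channels, V x n_eff
  chan_latent_id <- integer(0)
  seeds_extra <- list()
  for (e in effects$effects) {
    .assert(all(mask[e$roi]), "effect ROI extends outside the brain mask")
    par <- e$base + e$beta_dx * dx + e$beta_sex * sx + e$beta_int * dx * sx
    .assert(par >= 0 && par <= 1, "injected coupling out of [0, 1]")
    if (e$channel == "vmhc") {
      coupling[e$roi] <- par
    } else if (e$channel == "falff") {
      frac_inband[e$roi] <- par
    } else {                                      # reho / pcc_ifc / dc
      w2 <- numeric(V); w2[e$roi] <- par
      chan_w2 <- cbind(chan_w2, w2)
      if (e$channel == "pcc_ifc" && !is.null(e$seed)) {
        seeds_extra[[length(seeds_extra) + 1L]] <-
          list(col = ncol(chan_w2), voxels = e$seed)
      }
    }
  }

  ## --- site batch effect on the link scale ------------------------------
  if (!is.null(site)) {
    z <- atanh(pmin(coupling, 1 - 1e-12))
    z[mask] <- site$delta * z[mask] + site$gamma
    coupling[mask] <- tanh(z[mask])
    fz <- frac_inband > 0
    if (any(fz)) {
      lg <- qlogis(pmin(frac_inband[fz], 1 - 1e-12))
      frac_inband[fz] <- plogis(site$delta * lg + site$gamma)
    }
  }

  ## --- variance budget ---------------------------------------------------
  w2_pair <- abs(coupling)
  w2_chan_tot <- if (is.null(chan_w2)) numeric(V) else rowSums(chan_w2)
  w2_unique <- 1 - w2_pair - w2_chan_tot - frac_inband
  .assert(all(w2_unique > -1e-12),
          "channel variance fractions exceed 1 at some voxel")
  w2_unique <- pmax(w2_unique, 0)

  ## --- assemble ----------------------------------------------------------
  y <- .ar1_noise(Tt, V, phi) * rep(sqrt(w2_unique), each = Tt)
  mi <- .mirror_index(dims)
  left <- which(seq_len(V) < mi)                  # one index per mirror pair
  pair_of <- integer(V)
  pair_of[left] <- seq_along(left)
  pair_of[mi[left]] <- seq_along(left)
  S <- .ar1_noise(Tt, length(left), phi)
  ## negative coupling: flip the latent sign on one pair member only
  w_pair <- sqrt(w2_pair)
  w_pair[left] <- sign(coupling[left]) * w_pair[left]
  use <- which(w_pair != 0)
  if (length(use)) {
    y[, use] <- y[, use] + S[, pair_of[use]] * rep(w_pair[use], each = Tt)
  }
  if (!is.null(chan_w2)) {
    L <- .ar1_noise(Tt, ncol(chan_w2), phi)
    for (j in seq_len(ncol(chan_w2))) {
      use <- which(chan_w2[, j] > 0)
      y[, use] <- y[, use] + matrix(L[, j], Tt, length(use)) *
        rep(sqrt(chan_w2[use, j]), each = Tt)
      ## wire the channel latent into its seed region (strong, fixed weight)
      for (sd_e in seeds_extra) {
        if (sd_e$col == j) {
          sv <- sd_e$voxels
          y[, sv] <- sqrt(0.2) * y[, sv] +
            sqrt(0.8) * matrix(L[, j], Tt, length(sv))
        }
      }
    }
  }
  fz <- which(frac_inband > 0)
  if (length(fz)) {
    B <- .inband_noise(Tt, length(fz), spec$tr)
    y[, fz] <- y[, fz] + B * rep(sqrt(frac_inband[fz]), each = Tt)
  }

  ## --- motion-locked nuisance --------------------------------------------
  if (!is.null(motion) && any(abs(diff(motion)) > 0)) {
    d <- rbind(0, diff(motion))
    comb <- motion %*% rep(1, 6L) + d %*% rep(2, 6L)
    if (sd(comb) > 0) {
      m <- as.numeric(scale(comb))
      y <- sqrt(1 - motion_weight^2) * y + motion_weight * m
    }
  }

  out <- bold_image(y, dims, spec$voxel_size, spec$tr, mask)
  attr(out, "coupling") <- coupling
  attr(out, "frac_inband") <- frac_inband
  out
}
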