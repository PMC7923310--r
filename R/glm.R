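#' Build the group-level design matrix
#'
#' Columns: intercept, `dx` (NT = 0, ASD = 1), `sex` (M = 0, F = 1), their
#' interaction `dx_by_sex`, mean-centered `age` and `mfd`, and optionally
#' mean-centered `fiq` (the supplementary nuisance variant).
#'
#' @param table phenotype table with `dx`, `sex`, `age`, `mfd` (and `fiq`
#'   when requested).
#' @param include_fiq add the full-scale-IQ nuisance column.
#' @return `N x p` design matrix with named columns; rank-checked.
#' @export
build_design <- function(table, include_fiq = FALSE) {
  need <- c("dx", "sex", "age", "mfd", if (include_fiq) "fiq")
  .assert(all(need %in% names(table)),
          paste("missing columns:",
                paste(setdiff(need, names(table)), collapse = ", ")))
  dx <- as.integer(table$dx == "ASD")
  sx <- as.integer(table$sex == "F")
  .assert(length(unique(dx)) == 2L && length(unique(sx)) == 2L,
          "both levels of dx and sex must be present")
  X <- cbind(intercept = 1, dx = dx, sex = sx, dx_by_sex = dx * sx,
             age = table$age - mean(table$age),
             mfd = table$mfd - mean(table$mfd))
  if (include_fiq) X <- cbind(X, fiq = table$fiq - mean(table$fiq))
  .assert(qr(X)$rank == ncol(X), "design matrix is rank deficient")
  X
}

#' Voxel-wise general linear model
#'
#' Ordinary least squares at every voxel with t statistics for the
#' requested contrasts, converted to signed Z scores by CDF matching
#' (`Z = qnorm(pt(t, df))` computed on the log scale for tail accuracy).
#' Residuals are returned for smoothness estimation.
#'
#' @param data `N x V` subject-by-voxel matrix.
#' @param design `N x p` design matrix from [build_design()].
#' @param contrasts named list of length-`p` contrast vectors; the default
#'   tests the `dx`, `sex` and `dx_by_sex` columns.
#' @return list of class `voxelwise_glm`: `z` (named list of Z vectors),
#'   `t`, `coef` (p x V), `df`, `residuals` (N x V), `sigma2`.
#' @export
voxelwise_glm <- function(data, design, contrasts = NULL) {
  data <- as.matrix(data); design <- as.matrix(design)
  n <- nrow(data); p <- ncol(design)
  .assert(nrow(design) == n, "design rows must match data rows")
  .assert(n > p, "need more subjects than design columns")
  .assert(all(is.finite(data)), "non-finite data")
  if (is.null(contrasts)) {
    contrasts <- lapply(c("dx", "sex", "dx_by_sex"), function(nm) {
      cc <- numeric(p); cc[match(nm, colnames(design))] <- 1; cc
    })
    names(contrasts) <- c("dx", "sex", "dx_by_sex")
  }
  xtxi <- solve(crossprod(design))
  bet <- xtxi %*% crossprod(design, data)
  resid <- data - design %*% bet
  df <- n - p
  sigma2 <- colSums(resid^2) / df
  tmaps <- list(); zmaps <- list()
  for (nm in names(contrasts)) {
    cc <- contrasts[[nm]]
    se <- sqrt(pmax(as.numeric(crossprod(cc, xtxi) %*% cc) * sigma2, 0))
    tv <- numeric(ncol(data))
    ok <- se > 0
    tv[ok] <- as.numeric(crossprod(cc, bet))[ok] / se[ok]
    tmaps[[nm]] <- tv
    zmaps[[nm]] <- .t_to_z(tv, df)
  }
  structure(list(z = zmaps, t = tmaps, coef = bet, df = df,
                 residuals = resid, sigma2 = sigma2),
            class = "voxelwise_glm")
}

## signed t -> Z via upper-tail log CDF matching (symmetric, stable)
.t_to_z <- function(t, df) {
  sign(t) * qnorm(pt(abs(t), df, lower.tail = FALSE, log.p = TRUE),
                  lower.tail = FALSE, log.p = TRUE)
}

#' Estimate residual field smoothness
#'
#' Kiebel/Worsley-style estimator: the residual images are standardized
#' voxel-wise, and the variance of their spatial derivatives along each
#' axis gives the per-axis FWHM of an equivalent Gaussian autocorrelation,
#' `FWHM = sqrt(4 ln 2 / var(du/dx))`.  RESELs are the mask volume divided
#' by the product of the three FWHMs.
#'
#' @param residuals `N x V` residual matrix (N >= 10) over the full grid.
#' @param mask logical analysis mask (>= 100 voxels).
#' @param dims grid dimensions.
#' @param voxel_size voxel edge in mm.
#' @return list of class `smoothness_estimate`: `fwhm` (mm, per axis),
#'   `resels`, `n_mask`, `voxel_size`.
#' @export
estimate_smoothness <- function(residuals, mask, dims, voxel_size) {
  residuals <- as.matrix(residuals)
  .assert(nrow(residuals) >= 10L, "need at least 10 residual images")
  .assert(sum(mask) >= 100L, "mask must contain at least 100 voxels")
  sdv <- sqrt(colMeans(residuals^2))
  .assert(any(sdv[mask] > 0), "degenerate (constant) residuals")
  u <- residuals
  ok <- sdv > 0
  u[, ok] <- sweep(residuals[, ok, drop = FALSE], 2L, sdv[ok], "/")
  ijk <- .vox_ijk(seq_len(prod(dims)), dims)
  fwhm <- numeric(3L)
  for (ax in 1:3) {
    step <- c(1L, dims[1L], dims[1L] * dims[2L])[ax]
    here <- which(mask & ijk[, ax] < dims[ax] & mask[pmin(
      seq_len(prod(dims)) + step, prod(dims))])
    nb <- here + step
    good <- sdv[here] > 0 & sdv[nb] > 0
    here <- here[good]; nb <- nb[good]
    .assert(length(here) > 0, "no derivative pairs along an axis")
    d <- (u[, nb, drop = FALSE] - u[, here, drop = FALSE]) / voxel_size
    lambda <- mean(d^2)
    fwhm[ax] <- sqrt(4 * log(2) / lambda)
  }
  n_mask <- sum(mask)
  resels <- n_mask * voxel_size^3 / prod(fwhm)
  structure(list(fwhm = fwhm, resels = resels, n_mask = n_mask,
                 voxel_size = voxel_size),
            class = "smoothness_estimate")
}

#' @export
print.smoothness_estimate <- function(x, ...) {
  cat(sprintf("Smoothness: FWHM = (%.2f, %.2f, %.2f) mm, %.1f RESELs over %d voxels\n",
              x$fwhm[1L], x$fwhm[2L], x$fwhm[3L], x$resels, x$n_mask))
  invisible(x)
}

## connected components of a voxel set via neighbor-offset edge lists
.label_components <- function(voxels, dims, connectivity = 26L) {
  if (!length(voxels)) return(integer(0))
  off <- .neighbour_offsets(connectivity)
  off <- off[seq_len(nrow(off) / 2L), , drop = FALSE]  # half-space offsets
  inset <- logical(prod(dims)); inset[voxels] <- TRUE
  ijk <- .vox_ijk(voxels, dims)
  from <- integer(0); to <- integer(0)
  for (o in seq_len(nrow(off))) {
    ni <- ijk[, 1L] + off[o, 1L]
    nj <- ijk[, 2L] + off[o, 2L]
    nk <- ijk[, 3L] + off[o, 3L]
    okb <- ni >= 1L & ni <= dims[1L] & nj >= 1L & nj <= dims[2L] &
           nk >= 1L & nk <= dims[3L]
    if (!any(okb)) next
    nb <- .ijk_vox(cbind(ni[okb], nj[okb], nk[okb]), dims)
    hit <- inset[nb]
    from <- c(from, voxels[okb][hit])
    to <- c(to, nb[hit])
  }
  idx <- match(voxels, voxels)
  g <- igraph::graph_from_edgelist(
    cbind(match(from, voxels), match(to, voxels)), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(voxels) - igraph::vcount(g)))
  igraph::components(g)$membership[seq_along(voxels)]
}

#' Extract suprathreshold clusters from a Z map
#'
#' Connected components (26-connectivity by default) computed separately
#' for `Z > z_thresh` and `Z < -z_thresh`.
#'
#' @param z numeric Z vector over the full grid (or a `voxelwise_glm` Z
#'   entry).
#' @param dims grid dimensions.
#' @param mask logical analysis mask.
#' @param z_thresh cluster-forming threshold (default 3.1).
#' @param connectivity 6, 18 or 26.
#' @return data frame of class `cluster_table` with one row per cluster:
#'   `label`, `size`, `peak_z`, `peak_i/j/k`, `sign`, and the member
#'   voxels as a list column `voxels`.
#' @export
extract_clusters <- function(z, dims, mask, z_thresh = 3.1,
                             connectivity = 26L) {
  .assert(z_thresh > 0, "z_thresh must be positive")
  out <- list(); lab <- 0L
  for (sgn in c(1, -1)) {
    vox <- which(mask & sgn * z > z_thresh)
    if (!length(vox)) next
    memb <- .label_components(vox, dims, connectivity)
    for (m in sort(unique(memb))) {
      mv <- vox[memb == m]
      pk <- mv[which.max(sgn * z[mv])]
      ij <- .vox_ijk(pk, dims)
      lab <- lab + 1L
      out[[lab]] <- data.frame(label = lab, size = length(mv),
                               peak_z = z[pk], peak_i = ij[1L],
                               peak_j = ij[2L], peak_k = ij[3L],
                               sign = sgn)
      out[[lab]]$voxels <- list(mv)
    }
  }
  if (!length(out)) {
    res <- data.frame(label = integer(0), size = integer(0),
                      peak_z = numeric(0), peak_i = integer(0),
                      peak_j = integer(0), peak_k = integer(0),
                      sign = numeric(0))
    res$voxels <- list()
  } else {
    res <- do.call(rbind, out)
  }
  class(res) <- c("cluster_table", "data.frame")
  res
}

## Euler-characteristic density of a 3D Gaussian field at threshold u
.ec_density3 <- function(u) {
  (4 * log(2))^(3 / 2) / (2 * pi)^2 * (u^2 - 1) * exp(-u^2 / 2)
}

#' Gaussian-random-field cluster-level p value
#'
#' Expected-cluster-statistics correction: the expected number of clusters
#' above the threshold is the Euler-characteristic density times the
#' RESEL count; the expected cluster size is the expected suprathreshold
#' volume divided by the expected cluster count; observed sizes follow the
#' exponential tail `P(n >= k) = exp(-beta k^(2/3))` with
#' `beta = (Gamma(5/2) / E[n])^(2/3)`.  The corrected p value is
#' `1 - exp(-E[m] P(n >= k))`, monotone decreasing in cluster size.
#'
#' @param size cluster size in voxels (vectorized).
#' @param z_thresh cluster-forming threshold.
#' @param smoothness a [estimate_smoothness()] result.
#' @return corrected p value(s) in `[0, 1]`.
#' @export
grf_cluster_p <- function(size, z_thresh, smoothness) {
  .assert(inherits(smoothness, "smoothness_estimate"), "invalid smoothness")
  .assert(all(is.finite(smoothness$fwhm)) && all(smoothness$fwhm > 0) &&
          smoothness$resels > 0, "invalid smoothness")
  Em <- smoothness$resels * .ec_density3(z_thresh)
  EN <- smoothness$n_mask * pnorm(-z_thresh)
  En <- EN / Em
  beta <- (gamma(5 / 2) / En)^(2 / 3)
  pk <- exp(-beta * size^(2 / 3))
  pmin(pmax(1 - exp(-Em * pk), 0), 1)
}

#' Attach GRF-corrected p values to a cluster table
#'
#' @param clusters a [extract_clusters()] table.
#' @param z_thresh cluster-forming threshold used for extraction.
#' @param smoothness a [estimate_smoothness()] result.
#' @return the table with a `p_grf` column.
#' @export
grf_correct <- function(clusters, z_thresh, smoothness) {
  clusters$p_grf <- if (nrow(clusters)) {
    grf_cluster_p(clusters$size, z_thresh, smoothness)
  } else numeric(0)
  clusters
}

#' Freedman-Lane permutation null of the maximum cluster size
#'
#' Permutation oracle for the GRF correction: the reduced model (full
#' design minus the contrast column) is fitted, its residuals are permuted
#' as whole subject images, the permuted residuals plus reduced fitted
#' values are re-analyzed with the full model, and the maximum
#' suprathreshold cluster size across both signs is recorded.
#'
#' @param data `N x V` subject matrix over the full grid.
#' @param design group design matrix.
#' @param contrast name (or index) of the tested design column.
#' @param dims,mask grid geometry.
#' @param z_thresh cluster-forming threshold.
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed; the distribution is reproducible.
#' @param connectivity cluster connectivity.
#' @return sorted integer vector of `n_perm` max-cluster sizes.
#' @export
permutation_cluster_null <- function(data, design, contrast, dims, mask,
                                     z_thresh = 3.1, n_perm = 200L,
                                     seed = 1L, connectivity = 26L) {
  .assert(n_perm >= 100L, "need at least 100 permutations")
  design <- as.matrix(design)
  ci <- if (is.character(contrast)) match(contrast, colnames(design)) else contrast
  .assert(!is.na(ci), "contrast column not found")
  Xr <- design[, -ci, drop = FALSE]
  qr_r <- qr(Xr)
  fit_r <- Xr %*% qr.coef(qr_r, data)
  res_r <- data - fit_r
  cc <- numeric(ncol(design)); cc[ci] <- 1
  ctr <- setNames(list(cc), "perm")
  set.seed(seed)
  n <- nrow(data)
  out <- integer(n_perm)
  for (b in seq_len(n_perm)) {
    yp <- fit_r + res_r[sample(n), , drop = FALSE]
    g <- voxelwise_glm(yp, design, contrasts = ctr)
    cl <- extract_clusters(g$z$perm, dims, mask, z_thresh, connectivity)
    out[b] <- if (nrow(cl)) max(cl$size) else 0L
  }
  sort(out)
}

#' Permutation-corrected cluster p value
#'
#' @param size observed cluster size(s).
#' @param null_sizes sorted max-cluster null from
#'   [permutation_cluster_null()].
#' @return family-wise-error-corrected p value(s).
#' @export
permutation_cluster_p <- function(size, null_sizes) {
  vapply(size, function(k) {
    (1 + sum(null_sizes >= k)) / (1 + length(null_sizes))
  }, numeric(1))
}
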