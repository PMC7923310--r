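#' Friston 24-parameter motion regressor set
#'
#' Expands a 6-parameter motion trace into 24 columns: the 6 parameters,
#' their one-lag backward differences (first row zero), and the element-wise
#' squares of both sets.
#'
#' @param motion `T x 6` motion matrix.
#' @return `T x 24` matrix with named columns (`p1..p6`, `d1..d6`,
#'   `p1_sq..`, `d1_sq..`).
#' @export
friston24 <- function(motion) {
  motion <- as.matrix(motion)
  .assert(nrow(motion) >= 3L, "need at least 3 timepoints")
  .assert(ncol(motion) == 6L, "motion must have 6 columns")
  d <- rbind(0, diff(motion))
  out <- cbind(motion, d, motion^2, d^2)
  colnames(out) <- c(paste0("p", 1:6), paste0("d", 1:6),
                     paste0("p", 1:6, "_sq"), paste0("d", 1:6, "_sq"))
  out
}

#' CompCor nuisance components
#'
#' Principal-component time series of the variance-normalized voxel series
#' inside a noise compartment (e.g. the non-brain rim of a synthetic
#' volume, or CSF/white-matter masks in real data).  Zero-variance voxels
#' are dropped before the decomposition; each returned component has unit
#' variance.
#'
#' @param bold a [bold_image()].
#' @param noise_mask logical vector over the grid selecting noise voxels.
#' @param k number of components (default 5).
#' @return `T x k` matrix (0 columns if `k = 0`).
#' @export
compcor <- function(bold, noise_mask, k = 5L) {
  .assert(any(noise_mask), "empty noise mask")
  .assert(k < nrow(bold$data), "k must be below the number of timepoints")
  if (k == 0L) return(matrix(0, nrow(bold$data), 0L))
  x <- bold$data[, noise_mask, drop = FALSE]
  x <- sweep(x, 2L, colMeans(x))
  ss <- sqrt(colSums(x^2))
  x <- x[, ss > 0, drop = FALSE]
  .assert(ncol(x) > 0, "all noise-mask voxels have zero variance")
  x <- sweep(x, 2L, ss[ss > 0], "/")
  ## left singular vectors via the T x T Gram matrix (T << voxels)
  ev <- eigen(tcrossprod(x), symmetric = TRUE)
  comp <- ev$vectors[, seq_len(min(k, ncol(ev$vectors))), drop = FALSE]
  comp <- sweep(comp, 2L, apply(comp, 2L, sd), "/")
  colnames(comp) <- paste0("compcor", seq_len(ncol(comp)))
  comp
}

#' Assemble a nuisance design matrix
#'
#' Combines intercept, linear and quadratic trends, the 24-parameter motion
#' set, CompCor components, and (for the global-signal-regression pipeline
#' variant) the in-mask global mean series.  Constant columns other than
#' the intercept are removed before the rank check.
#'
#' @param bold a [bold_image()].
#' @param motion optional `T x 6` motion trace.
#' @param noise_mask optional CompCor noise compartment.
#' @param k_compcor number of CompCor components.
#' @param gsr include the global-signal column.
#' @return `T x k` design matrix with named columns.
#' @export
build_nuisance_design <- function(bold, motion = NULL, noise_mask = NULL,
                                  k_compcor = 5L, gsr = FALSE) {
  Tt <- nrow(bold$data)
  tlin <- seq_len(Tt) - (Tt + 1) / 2
  X <- cbind(intercept = 1, linear = tlin, quadratic = tlin^2)
  if (!is.null(motion)) X <- cbind(X, friston24(motion))
  if (!is.null(noise_mask)) X <- cbind(X, compcor(bold, noise_mask, k_compcor))
  if (gsr) X <- cbind(X, gs = rowMeans(bold$data[, bold$mask, drop = FALSE]))
  keep <- c(TRUE, apply(X[, -1L, drop = FALSE], 2L, sd) > 0)
  X <- X[, keep, drop = FALSE]
  .assert(qr(X)$rank == ncol(X), "nuisance design is rank deficient")
  X
}

#' Voxel-wise nuisance regression
#'
#' Removes the nuisance design from every voxel series by ordinary least
#' squares, returning the residual image.  Residuals are orthogonal to all
#' design columns.
#'
#' @param bold a [bold_image()].
#' @param design `T x k` full-rank design matrix.
#' @return a [bold_image()] of residuals.
#' @export
nuisance_regress <- function(bold, design) {
  design <- as.matrix(design)
  .assert(nrow(design) == nrow(bold$data),
          "design rows must equal timepoints")
  qrx <- qr(design)
  .assert(qrx$rank == ncol(design), "rank-deficient nuisance design")
  res <- bold$data - design %*% qr.coef(qrx, bold$data)
  bold_image(res, bold$dims, bold$voxel_size, bold$tr, bold$mask)
}

## ideal frequency-domain band-pass on a T x n matrix; removes DC
.fft_bandpass <- function(x, tr, low, high) {
  Tt <- nrow(x)
  k <- 0:(Tt - 1L)
  freq <- pmin(k, Tt - k) / (Tt * tr)
  keep <- freq >= low & freq <= high & k != 0L
  f <- mvfft(x)
  f[!keep, ] <- 0
  Re(mvfft(f, inverse = TRUE)) / Tt
}

#' Ideal band-pass temporal filter
#'
#' Hard frequency-domain filter: Fourier coefficients with frequency
#' outside `[low, high]` are zeroed (the DC term always is) and the series
#' is inverse-transformed.  Idempotent by construction.
#'
#' @param bold a [bold_image()].
#' @param low,high pass-band edges in Hz; defaults 0.01-0.1 Hz.
#' @return a filtered [bold_image()].
#' @export
bandpass <- function(bold, low = 0.01, high = 0.1) {
  nyq <- 1 / (2 * bold$tr)
  .assert(low >= 0 && low < high && high <= nyq + 1e-12,
          "band must satisfy 0 <= low < high <= Nyquist")
  out <- .fft_bandpass(bold$data, bold$tr, low, high)
  bold_image(out, bold$dims, bold$voxel_size, bold$tr, bold$mask)
}

## separable truncated-Gaussian kernel weights for one axis
.gauss_kernel <- function(fwhm, voxel_size) {
  sigma <- fwhm / (2 * sqrt(2 * log(2))) / voxel_size
  if (sigma == 0) return(1)
  r <- max(1L, ceiling(4 * sigma))
  w <- dnorm(-r:r, sd = sigma)
  w / sum(w)
}

## 1D convolution along one axis of a 3D volume with edge renormalization
.conv_axis <- function(vol, w, axis) {
  if (length(w) == 1L) return(vol)
  d <- dim(vol)
  perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  x <- aperm(vol, perm)
  n <- dim(x)[1L]
  m <- matrix(x, n)
  r <- (length(w) - 1L) / 2L
  acc <- matrix(0, n, ncol(m))
  for (s in -r:r) {
    src <- (1:n) - s
    ok <- src >= 1L & src <= n
    acc[ok, ] <- acc[ok, ] + w[s + r + 1L] * m[src[ok], ]
  }
  out <- array(acc, dim(x))
  aperm(out, order(perm))
}

#' Gaussian spatial smoothing
#'
#' Separable Gaussian convolution with kernel
#' `sigma = fwhm / (2 sqrt(2 ln 2)) / voxel_size` per axis.  Edge (and,
#' when a mask is supplied, out-of-mask) truncation is compensated by
#' normalized convolution, so constant inputs are reproduced exactly;
#' `fwhm = 0` is the identity.
#'
#' @param x 3D array, or 4D array (smoothed volume by volume), or a numeric
#'   vector interpreted on `dims`.
#' @param fwhm kernel full width at half maximum, mm.
#' @param voxel_size voxel edge, mm (> 0).
#' @param dims grid dimensions when `x` is a vector.
#' @param mask optional logical mask; smoothing is then restricted to and
#'   renormalized within the mask.
#' @return same shape as `x`.
#' @export
smooth_gaussian <- function(x, fwhm = 6, voxel_size = 3, dims = NULL,
                            mask = NULL) {
  .assert(voxel_size > 0, "voxel size must be positive")
  .assert(fwhm >= 0, "fwhm must be >= 0")
  vec_in <- is.null(dim(x))
  if (vec_in) {
    .assert(!is.null(dims), "dims required for vector input")
    x <- array(x, dims)
  }
  if (length(dim(x)) == 4L) {
    for (t in seq_len(dim(x)[4L])) {
      x[, , , t] <- smooth_gaussian(x[, , , t], fwhm, voxel_size,
                                    mask = mask)
    }
    return(x)
  }
  if (fwhm == 0) return(if (vec_in) as.numeric(x) else x)
  w <- .gauss_kernel(fwhm, voxel_size)
  run <- function(v) {
    v <- .conv_axis(v, w, 1L)
    v <- .conv_axis(v, w, 2L)
    .conv_axis(v, w, 3L)
  }
  if (is.null(mask)) {
    num <- run(x)
    den <- run(array(1, dim(x)))
  } else {
    m <- array(as.numeric(mask), dim(x))
    num <- run(x * m)
    den <- run(m)
  }
  out <- ifelse(den > 1e-12, num / den, 0)
  if (!is.null(mask)) out <- out * array(as.numeric(mask), dim(x))
  out <- array(out, dim(x))
  if (vec_in) as.numeric(out) else out
}

#' Run the discovery denoising pipeline on one subject
#'
#' Nuisance regression (trends + 24 motion parameters + CompCor, plus the
#' global signal for the GSR variant) followed by 0.01-0.1 Hz band-pass
#' filtering.  The unfiltered residual image is returned alongside because
#' the fractional amplitude metric must consume the regressed but
#' unfiltered series.
#'
#' @param bold a [bold_image()].
#' @param motion optional `T x 6` motion trace.
#' @param noise_mask CompCor compartment; defaults to the non-brain voxels.
#' @param gsr use the global-signal-regression pipeline variant.
#' @param band pass band in Hz.
#' @param k_compcor number of CompCor components.
#' @return list: `filtered` (band-passed residuals, input to all metrics
#'   but fALFF) and `unfiltered` (residuals only, input to fALFF).
#' @export
denoise_subject <- function(bold, motion = NULL, noise_mask = NULL,
                            gsr = FALSE, band = c(0.01, 0.1),
                            k_compcor = 5L) {
  noise_mask <- noise_mask %||% !bold$mask
  X <- build_nuisance_design(bold, motion, noise_mask, k_compcor, gsr)
  res <- nuisance_regress(bold, X)
  list(filtered = bandpass(res, band[1L], band[2L]), unfiltered = res)
}
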