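#' Metric map container
#'
#' @param values numeric vector over the full grid (zero outside mask).
#' @param metric one of `pcc_ifc`, `vmhc`, `reho`, `dc`, `falff`.
#' @param dims grid dimensions.
#' @param mask logical mask.
#' @param standardization `"fisher_z"`, `"zscore"` or `"raw"`.
#' @param flags optional integer vector of flagged voxels (e.g. too few
#'   neighbors, zero-variance series).
#' @return object of class `metric_map`.
#' @export
metric_map <- function(values, metric, dims, mask,
                       standardization = "raw", flags = integer(0)) {
  .assert(metric %in% c("pcc_ifc", "vmhc", "reho", "dc", "falff"),
          "unknown metric name")
  values[!mask] <- 0
  .assert(all(is.finite(values[mask])), "non-finite values inside mask")
  structure(list(values = values, metric = metric, dims = dims,
                 mask = mask, standardization = standardization,
                 flags = flags),
            class = "metric_map")
}

#' @export
print.metric_map <- function(x, ...) {
  v <- x$values[x$mask]
  cat(sprintf("%s map (%s): %d in-mask voxels, range [%.3f, %.3f]\n",
              x$metric, x$standardization, sum(x$mask), min(v), max(v)))
  invisible(x)
}

.fisher_z <- function(r, clip = 1 - 1e-7) atanh(pmin(pmax(r, -clip), clip))

## correlations between each column of x and the vector s
.cor_with <- function(x, s) {
  s <- s - mean(s)
  xc <- sweep(x, 2L, colMeans(x))
  num <- as.numeric(crossprod(xc, s))
  den <- sqrt(colSums(xc^2) * sum(s^2))
  r <- numeric(ncol(x))
  ok <- den > 0
  r[ok] <- num[ok] / den[ok]
  list(r = r, ok = ok)
}

#' Seed-based intrinsic functional connectivity
#'
#' Pearson correlation of every in-mask voxel series with the mean series
#' of a seed region (e.g. a posterior-cingulate sphere), Fisher-z
#' transformed with `r` clipped to `1 - 1e-7` in magnitude.
#'
#' @param bold a denoised, band-passed [bold_image()].
#' @param seed_mask logical vector or voxel indices of the seed region.
#' @return a `metric_map` (`pcc_ifc`, Fisher z).
#' @export
seed_ifc <- function(bold, seed_mask) {
  if (!is.logical(seed_mask)) {
    sm <- rep(FALSE, prod(bold$dims)); sm[seed_mask] <- TRUE
    seed_mask <- sm
  }
  .assert(any(seed_mask), "empty seed mask")
  .assert(all(bold$mask[seed_mask]), "seed must lie inside the brain mask")
  s <- rowMeans(bold$data[, seed_mask, drop = FALSE])
  .assert(sd(s) > 0, "zero-variance seed series")
  vox <- which(bold$mask)
  cc <- .cor_with(bold$data[, vox, drop = FALSE], s)
  vals <- numeric(prod(bold$dims))
  vals[vox] <- .fisher_z(cc$r)
  metric_map(vals, "pcc_ifc", bold$dims, bold$mask, "fisher_z",
             flags = vox[!cc$ok])
}

#' Voxel-mirrored homotopic connectivity
#'
#' Fisher-z of the Pearson correlation between each voxel's series and the
#' series of its left-right mirror voxel (index reflection about the x
#' mid-plane; the grid is assumed registered to a symmetric template).
#' The map is exactly mirror-symmetric by construction.  Voxels whose own
#' or mirror series has zero variance get value 0 and are flagged.
#'
#' @param bold a denoised, band-passed [bold_image()] on an even-`nx` grid.
#' @return a `metric_map` (`vmhc`, Fisher z).
#' @export
vmhc <- function(bold) {
  .assert(bold$dims[1L] %% 2L == 0L, "nx must be even for mirror pairs")
  mi <- .mirror_index(bold$dims)
  vox <- which(bold$mask & bold$mask[mi])
  left <- vox[vox < mi[vox]]
  x <- bold$data[, left, drop = FALSE]
  y <- bold$data[, mi[left], drop = FALSE]
  xc <- sweep(x, 2L, colMeans(x)); yc <- sweep(y, 2L, colMeans(y))
  num <- colSums(xc * yc)
  den <- sqrt(colSums(xc^2) * colSums(yc^2))
  r <- numeric(length(left)); ok <- den > 0
  r[ok] <- num[ok] / den[ok]
  vals <- numeric(prod(bold$dims))
  vals[left] <- .fisher_z(r)
  vals[mi[left]] <- vals[left]
  flags <- c(left[!ok], mi[left][!ok])
  metric_map(vals, "vmhc", bold$dims, bold$mask & bold$mask[mi],
             "fisher_z", flags = flags)
}

#' Kendall's coefficient of concordance
#'
#' Agreement of `K` time series over `n` timepoints:
#' `W = 12 S / (K^2 (n^3 - n) - K * sum(T_j))` where `S` is the sum of
#' squared deviations of the rank sums and `T_j = sum(t^3 - t)` over tied
#' groups of series `j` (midrank tie correction).
#'
#' @param series `n x K` matrix, one column per series.
#' @return `W` in `[0, 1]`.
#' @export
kendall_w <- function(series) {
  series <- as.matrix(series)
  n <- nrow(series); K <- ncol(series)
  .assert(K >= 2L, "need at least 2 series")
  .assert(n >= 3L, "need at least 3 timepoints")
  R <- apply(series, 2L, rank)
  Ri <- rowSums(R)
  S <- sum((Ri - mean(Ri))^2)
  Tj <- apply(series, 2L, function(x) {
    t <- table(x); sum(t^3 - t)
  })
  den <- K^2 * (n^3 - n) - K * sum(Tj)
  .assert(den > 0, "tie correction yields zero denominator (constant series)")
  12 * S / den
}

#' Regional homogeneity map
#'
#' Kendall's W of each voxel's series with its in-mask neighbors under 7-,
#' 19- or 27-voxel connectivity (voxel itself included).  Voxels with
#' fewer than 4 available neighbors are set to 0 and flagged; edge voxels
#' with a partial neighborhood are computed with the reduced `K` and
#' flagged.
#'
#' @param bold a denoised, band-passed [bold_image()].
#' @param neighborhood 7, 19 or 27.
#' @return a `metric_map` (`reho`, raw `W` in `[0, 1]`).
#' @export
reho <- function(bold, neighborhood = 27L) {
  .assert(neighborhood %in% c(7L, 19L, 27L),
          "neighborhood must be one of 7, 19, 27")
  conn <- c("7" = 6L, "19" = 18L, "27" = 26L)[as.character(neighborhood)]
  off <- rbind(c(0L, 0L, 0L), .neighbour_offsets(conn))
  dims <- bold$dims; V <- prod(dims); Tt <- nrow(bold$data)
  mask <- bold$mask
  ## per-voxel midranks and tie terms, in-mask columns only
  R <- matrix(0, Tt, V)
  tie <- numeric(V)
  vox <- which(mask)
  R[, vox] <- apply(bold$data[, vox, drop = FALSE], 2L, rank)
  tie[vox] <- apply(bold$data[, vox, drop = FALSE], 2L, function(x) {
    t <- table(x); sum(t^3 - t)
  })
  ijk <- .vox_ijk(seq_len(V), dims)
  sumR <- matrix(0, Tt, V)
  Kcnt <- numeric(V)
  tsum <- numeric(V)
  for (o in seq_len(nrow(off))) {
    ni <- ijk[, 1L] + off[o, 1L]
    nj <- ijk[, 2L] + off[o, 2L]
    nk <- ijk[, 3L] + off[o, 3L]
    okb <- ni >= 1L & ni <= dims[1L] & nj >= 1L & nj <= dims[2L] &
           nk >= 1L & nk <= dims[3L]
    tgt <- which(okb & mask)
    nb <- .ijk_vox(cbind(ni[tgt], nj[tgt], nk[tgt]), dims)
    inm <- mask[nb]
    tgt <- tgt[inm]; nb <- nb[inm]
    sumR[, tgt] <- sumR[, tgt] + R[, nb]
    Kcnt[tgt] <- Kcnt[tgt] + 1
    tsum[tgt] <- tsum[tgt] + tie[nb]
  }
  vals <- numeric(V)
  flags <- integer(0)
  ok <- mask & (Kcnt - 1) >= 4          # >= 4 neighbors besides the voxel
  low <- which(mask & !ok)
  flags <- c(flags, low)
  partial <- which(ok & Kcnt < neighborhood)
  flags <- c(flags, partial)
  use <- which(ok)
  if (length(use)) {
    K <- Kcnt[use]
    S <- colSums((sumR[, use, drop = FALSE] -
                  matrix(K * (Tt + 1) / 2, Tt, length(use),
                         byrow = TRUE))^2)
    den <- K^2 * (Tt^3 - Tt) - K * tsum[use]
    good <- den > 0
    vals[use[good]] <- 12 * S[good] / den[good]
    flags <- c(flags, use[!good])
  }
  metric_map(vals, "reho", dims, mask, "raw", flags = sort(unique(flags)))
}

#' Degree centrality map
#'
#' For every in-mask voxel, the count (binarized) or sum (weighted) of
#' positive correlations exceeding `r_threshold` with all other in-mask
#' voxels, self-correlation excluded.
#'
#' @param bold a denoised, band-passed [bold_image()].
#' @param r_threshold correlation threshold (default 0.25), `|r| < 1`.
#' @param binarize count connections (`TRUE`) or sum their weights.
#' @param block column block size of the correlation computation.
#' @return a `metric_map` (`dc`, raw counts/sums).
#' @export
degree_centrality <- function(bold, r_threshold = 0.25, binarize = TRUE,
                              block = 2048L) {
  .assert(abs(r_threshold) < 1, "|r_threshold| must be < 1")
  vox <- which(bold$mask)
  .assert(length(vox) >= 2L, "need at least 2 in-mask voxels")
  x <- bold$data[, vox, drop = FALSE]
  xc <- sweep(x, 2L, colMeans(x))
  ss <- sqrt(colSums(xc^2))
  ss[ss == 0] <- Inf                    # zero-variance voxels correlate 0
  xs <- sweep(xc, 2L, ss, "/")
  n <- length(vox)
  deg <- numeric(n)
  for (st in seq(1L, n, by = block)) {
    en <- min(st + block - 1L, n)
    r <- crossprod(xs, xs[, st:en, drop = FALSE])
    hit <- r > r_threshold
    if (binarize) {
      deg[st:en] <- colSums(hit) - 1    # remove self (r = 1 > threshold)
    } else {
      deg[st:en] <- colSums(r * hit) - 1
    }
  }
  vals <- numeric(prod(bold$dims))
  vals[vox] <- deg
  metric_map(vals, "dc", bold$dims, bold$mask, "raw")
}

#' Fractional amplitude of low-frequency fluctuations
#'
#' Per voxel, the sum of Fourier amplitudes (square-root power) within the
#' low-frequency band divided by the sum over the whole positive-frequency
#' range; the DC term is excluded from both.  Consumes the nuisance-
#' regressed but NOT band-passed series.
#'
#' @param bold_unfiltered a regressed, unfiltered [bold_image()].
#' @param band numerator band in Hz (default 0.01-0.1, matching the
#'   pipeline's filter band).
#' @return a `metric_map` (`falff`, raw fraction in `[0, 1]`).
#' @export
falff <- function(bold_unfiltered, band = c(0.01, 0.1)) {
  bold <- bold_unfiltered
  Tt <- nrow(bold$data)
  nyq <- 1 / (2 * bold$tr)
  .assert(band[1L] >= 0 && band[1L] < band[2L] && band[2L] <= nyq + 1e-12,
          "band must lie within (0, Nyquist]")
  vox <- which(bold$mask)
  amp <- Mod(mvfft(bold$data[, vox, drop = FALSE]))
  kmax <- floor(Tt / 2)
  freq <- (1:kmax) / (Tt * bold$tr)
  amp <- amp[2:(kmax + 1L), , drop = FALSE]
  tot <- colSums(amp)
  inb <- colSums(amp[freq >= band[1L] & freq <= band[2L], , drop = FALSE])
  vals <- numeric(prod(bold$dims))
  ok <- tot > 0
  vals[vox[ok]] <- inb[ok] / tot[ok]
  metric_map(vals, "falff", bold$dims, bold$mask, "raw",
             flags = vox[!ok])
}

#' Standardize a metric map for group analysis
#'
#' Amplitude/count metrics (`reho`, `dc`, `falff`) are z-scored within the
#' mask so subject maps are scale-free; correlation metrics (`pcc_ifc`,
#' `vmhc`) already live on the Fisher-z scale and pass through unchanged.
#'
#' @param map a `metric_map`.
#' @return a `metric_map` with updated `standardization` tag.
#' @export
standardize_map <- function(map) {
  if (map$standardization == "fisher_z") return(map)
  v <- map$values[map$mask]
  .assert(sd(v) > 0, "zero variance inside mask")
  out <- map
  out$values[map$mask] <- (v - mean(v)) / sd(v)
  out$standardization <- "zscore"
  out
}
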