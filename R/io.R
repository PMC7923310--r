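#' Write and read 4D BOLD volumes as NIfTI-1
#'
#' @param bold a [bold_image()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `write_bold_nifti` returns `path` invisibly; `read_bold_nifti`
#'   returns a [bold_image()] (mask: non-constant voxels unless given).
#' @export
write_bold_nifti <- function(bold, path) {
  arr <- as_bold_array(bold)
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(rep(bold$voxel_size, 3L), bold$tr)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_bold_nifti
#' @param tr repetition time override (seconds); default from the header.
#' @param mask optional logical mask.
#' @export
read_bold_nifti <- function(path, tr = NULL, mask = NULL) {
  img <- RNifti::readNifti(path)
  pd <- attr(img, "pixdim") %||% RNifti::pixdim(img)
  arr <- array(as.numeric(img), dim(img))
  .assert(length(dim(arr)) == 4L, "expected a 4D NIfTI volume")
  tr <- tr %||% (if (length(pd) >= 4L && pd[4L] > 0) pd[4L] else 1)
  b <- bold_image(arr, dim(arr)[1:3], voxel_size = pd[1L], tr = tr)
  if (!is.null(mask)) b$mask <- mask
  b
}

#' Write a 3D metric map as NIfTI-1
#'
#' @param map a [metric_map()].
#' @param path output path.
#' @param voxel_size voxel edge in mm.
#' @return `path`, invisibly.
#' @export
write_metric_nifti <- function(map, path, voxel_size = 3) {
  arr <- array(map$values, map$dims)
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rep(voxel_size, 3L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Motion-parameter text IO
#'
#' Six-column whitespace-delimited text, one row per timepoint
#' (translations in mm, rotations in rad).
#'
#' @param motion `T x 6` matrix.
#' @param path file path.
#' @return `write_motion_params` returns `path` invisibly;
#'   `read_motion_params` returns the `T x 6` matrix.
#' @export
write_motion_params <- function(motion, path) {
  write.table(format(motion, digits = 10, scientific = TRUE), path,
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_motion_params
#' @export
read_motion_params <- function(path) {
  m <- as.matrix(read.delim(path, header = FALSE, sep = ""))
  .assert(ncol(m) == 6L, "expected 6 motion columns")
  colnames(m) <- c("trans_x", "trans_y", "trans_z",
                   "rot_x", "rot_y", "rot_z")
  unname(m)
  m
}

#' Phenotype table TSV IO
#'
#' @param table phenotype data frame.
#' @param path file path.
#' @return `write_phenotypes` returns `path` invisibly;
#'   `read_phenotypes` returns the table with `dx`/`sex` as factors.
#' @export
write_phenotypes <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if ("dx" %in% names(tab)) tab$dx <- factor(tab$dx, levels = c("NT", "ASD"))
  if ("sex" %in% names(tab)) tab$sex <- factor(tab$sex, levels = c("M", "F"))
  tab
}

#' Write a cluster table as TSV
#'
#' Label, size, peak Z, peak voxel indices and mm coordinates, sign and
#' corrected p value; the member-voxel list column is dropped.
#'
#' @param clusters a cluster table from [extract_clusters()] /
#'   [grf_correct()].
#' @param path file path.
#' @param voxel_size voxel edge (mm) for the mm coordinates.
#' @return `path`, invisibly.
#' @export
write_cluster_table <- function(clusters, path, voxel_size = 3) {
  tab <- clusters[, setdiff(names(clusters), "voxels"), drop = FALSE]
  tab$peak_x_mm <- (clusters$peak_i - 1) * voxel_size
  tab$peak_y_mm <- (clusters$peak_j - 1) * voxel_size
  tab$peak_z_mm <- (clusters$peak_k - 1) * voxel_size
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize a ComBat fit to JSON
#'
#' @param fit a [combat_fit()].
#' @param path file path ending in `.json`.
#' @return `write_combat_fit` returns `path` invisibly; `read_combat_fit`
#'   returns a `combat_fit` usable by [combat_apply()] (with the original
#'   batch labels and design).
#' @export
write_combat_fit <- function(fit, path) {
  x <- list(alpha_hat = fit$alpha_hat, beta_hat = fit$beta_hat,
            gamma_star = fit$gamma_star, delta_star = fit$delta_star,
            var_pooled = fit$var_pooled, priors = fit$priors,
            batch_levels = fit$batch_levels,
            batch = as.character(fit$batch), design = fit$design,
            zero_var = fit$zero_var)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_combat_fit
#' @export
read_combat_fit <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_mat <- function(m) if (is.null(dim(m)) && length(m)) {
    matrix(m, nrow = length(x$batch_levels))
  } else as.matrix(m)
  structure(list(alpha_hat = x$alpha_hat,
                 beta_hat = if (length(x$beta_hat)) as.matrix(x$beta_hat)
                            else matrix(0, 0L, length(x$alpha_hat)),
                 gamma_star = as_mat(x$gamma_star),
                 delta_star = as_mat(x$delta_star),
                 var_pooled = x$var_pooled, priors = x$priors,
                 batch_levels = x$batch_levels,
                 batch = factor(x$batch, levels = x$batch_levels),
                 design = if (length(x$design)) as.matrix(x$design) else NULL,
                 zero_var = if (length(x$zero_var)) x$zero_var else integer(0)),
            class = "combat_fit")
}

#' Unit-variance smooth Gaussian null fields
#'
#' White noise convolved with a Gaussian kernel and standardized by the
#' exact per-voxel kernel norm, giving fields with marginal N(0, 1)
#' distribution and known smoothness; used to calibrate the cluster-level
#' correction.
#'
#' @param n number of fields.
#' @param dims grid dimensions.
#' @param fwhm kernel FWHM in mm.
#' @param voxel_size voxel edge in mm.
#' @return `n x prod(dims)` matrix, one field per row.
#' @export
simulate_smooth_fields <- function(n, dims, fwhm = 9, voxel_size = 3) {
  w <- .gauss_kernel(fwhm, voxel_size)
  ## per-voxel variance of the truncated separable convolution of N(0,1)
  run2 <- function(v, wt) {
    v <- .conv_axis(v, wt, 1L); v <- .conv_axis(v, wt, 2L)
    .conv_axis(v, wt, 3L)
  }
  sd_map <- sqrt(run2(array(1, dims), w^2))
  out <- matrix(0, n, prod(dims))
  for (i in seq_len(n)) {
    x <- array(rnorm(prod(dims)), dims)
    y <- run2(x, w)                      # plain truncated convolution
    out[i, ] <- as.numeric(y / sd_map)
  }
  out
}
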