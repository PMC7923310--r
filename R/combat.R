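#' Fit the parametric empirical-Bayes ComBat model
#'
#' Location/scale batch-effect model for a subjects-by-voxels metric
#' matrix.  Voxel data are standardized by the covariate-adjusted grand
#' mean and pooled variance; per-site location (`gamma`) and scale
#' (`delta`) are estimated and then shrunk toward parametric priors
#' (normal for location, inverse-gamma for scale) by iterating the
#' conditional posterior means to convergence (relative change < 1e-4).
#' Covariates supplied in `design` (e.g. diagnosis, sex, their
#' interaction, age, motion) are protected: their fitted effects are
#' removed before standardization and restored afterwards, so the batch
#' step cannot absorb them.
#'
#' Site locations are identified only up to a per-voxel constant (the
#' sample-size-weighted mean across sites is absorbed into the grand
#' mean), so `gamma_star` estimates the centered site effect on the
#' pooled-standardized scale.
#'
#' @param data `n x V` matrix, subjects in rows.
#' @param batch factor or character vector of site labels, length `n`.
#' @param design optional `n x q` covariate matrix WITHOUT an intercept or
#'   site indicators.
#' @param tol relative convergence tolerance of the EB iteration.
#' @return object of class `combat_fit` with elements `alpha_hat`
#'   (grand mean per voxel), `beta_hat` (`q x V` covariate effects),
#'   `gamma_star`, `delta_star` (`I x V` shrunk site parameters),
#'   `var_pooled`, hyperparameter list `priors`, `batch_levels`, `batch`,
#'   `design`, and `zero_var` (flagged pass-through voxels).
#' @export
combat_fit <- function(data, batch, design = NULL, tol = 1e-4) {
  data <- as.matrix(data)
  n <- nrow(data); V <- ncol(data)
  batch <- factor(batch)
  .assert(length(batch) == n, "batch length must match rows")
  ni <- table(batch)
  .assert(all(ni >= 2L), "every site needs at least 2 subjects")
  B <- outer(batch, levels(batch), `==`) * 1      # one-hot site design
  if (!is.null(design)) {
    design <- as.matrix(design)
    .assert(nrow(design) == n, "design rows must match data")
    X <- cbind(B, design)
  } else {
    X <- B
  }
  qrx <- qr(X)
  .assert(qrx$rank == ncol(X),
          "rank-deficient design (site indicators must not be in design)")
  beta_full <- qr.coef(qrx, data)                 # (I + q) x V
  I <- nlevels(batch)
  gamma_hat0 <- beta_full[seq_len(I), , drop = FALSE]
  beta_cov <- if (ncol(X) > I) {
    beta_full[-seq_len(I), , drop = FALSE]
  } else {
    matrix(0, 0L, V)
  }
  alpha_hat <- as.numeric(crossprod(as.numeric(ni) / n, gamma_hat0))
  fitted <- X %*% beta_full
  var_pooled <- colMeans((data - fitted)^2)
  zero_var <- which(var_pooled <= .Machine$double.eps * 100 *
                      max(var_pooled, 1e-300))
  vp <- var_pooled
  vp[zero_var] <- 1                               # pass-through voxels
  stand_mean <- matrix(alpha_hat, n, V, byrow = TRUE)
  if (nrow(beta_cov) > 0) stand_mean <- stand_mean + design %*% beta_cov
  Z <- (data - stand_mean) / matrix(sqrt(vp), n, V, byrow = TRUE)

  gamma_hat <- rowsum(Z, batch) / as.numeric(ni)
  delta_hat <- (rowsum(Z^2, batch) -
                as.numeric(ni) * gamma_hat^2) / pmax(as.numeric(ni) - 1, 1)

  ## parametric priors (method of moments, one set per site)
  gamma_bar <- rowMeans(gamma_hat)
  tau2 <- apply(gamma_hat, 1L, var)
  dm <- rowMeans(delta_hat)
  ds2 <- apply(delta_hat, 1L, var)
  lambda <- (2 * ds2 + dm^2) / ds2                # inverse-gamma shape
  theta <- (dm * ds2 + dm^3) / ds2                # inverse-gamma scale

  gamma_star <- gamma_hat
  delta_star <- delta_hat
  if (I == 1L) {
    ## a single site carries no batch structure: identity adjustment
    gamma_star[] <- 0
    delta_star[] <- 1
    tau2[] <- 0; lambda[] <- NA_real_; theta[] <- NA_real_
  } else for (i in seq_len(I)) {
    if (!is.finite(lambda[i]) || !is.finite(theta[i]) ||
        !is.finite(tau2[i]) || ds2[i] <= 0) {
      next                               # degenerate prior: no shrinkage
    }
    idx <- which(batch == levels(batch)[i])
    nb <- length(idx)
    g <- gamma_hat[i, ]; d <- delta_hat[i, ]
    repeat {
      g_new <- (tau2[i] * nb * gamma_hat[i, ] + d * gamma_bar[i]) /
               (tau2[i] * nb + d)
      ss <- colSums((Z[idx, , drop = FALSE] -
                     matrix(g_new, nb, V, byrow = TRUE))^2)
      d_new <- (theta[i] + 0.5 * ss) / (nb / 2 + lambda[i] - 1)
      change <- max(abs(g_new - g) / pmax(abs(g), 1e-8),
                    abs(d_new - d) / pmax(abs(d), 1e-8))
      g <- g_new; d <- d_new
      if (change < tol) break
    }
    gamma_star[i, ] <- g
    delta_star[i, ] <- d
  }
  .assert(all(delta_star > 0), "non-positive shrunk scale estimate")
  structure(list(alpha_hat = alpha_hat, beta_hat = beta_cov,
                 gamma_star = gamma_star, delta_star = delta_star,
                 gamma_hat = gamma_hat, delta_hat = delta_hat,
                 var_pooled = vp,
                 priors = list(gamma_bar = gamma_bar, tau2 = tau2,
                               lambda = lambda, theta = theta),
                 batch_levels = levels(batch), batch = batch,
                 design = design, zero_var = zero_var),
            class = "combat_fit")
}

#' @export
print.combat_fit <- function(x, ...) {
  cat("ComBat fit:", length(x$batch_levels), "sites,",
      length(x$alpha_hat), "voxels,",
      length(x$zero_var), "zero-variance pass-through voxels\n")
  cat("  mean |gamma*| per site:",
      paste(sprintf("%.3f", rowMeans(abs(x$gamma_star))), collapse = ", "),
      "\n")
  invisible(x)
}

#' Apply a fitted ComBat adjustment
#'
#' Removes the shrunk site location/scale from the standardized data and
#' restores the protected covariate effects and grand mean.  Voxels
#' flagged as zero pooled variance pass through unchanged.
#'
#' @param data `n x V` matrix (defaults semantics: the data the fit was
#'   estimated on).
#' @param fit a [combat_fit()].
#' @param batch site labels for `data` rows (default: those stored in the
#'   fit); every label must have been seen when fitting.
#' @param design covariate matrix aligned with `data` (default: stored).
#' @return harmonized `n x V` matrix.
#' @export
combat_apply <- function(data, fit, batch = NULL, design = NULL) {
  data <- as.matrix(data)
  batch <- batch %||% fit$batch
  design <- design %||% fit$design
  batch <- factor(batch, levels = fit$batch_levels)
  .assert(!anyNA(batch), "unseen site label")
  n <- nrow(data); V <- ncol(data)
  .assert(length(batch) == n, "batch length must match rows")
  .assert(V == length(fit$alpha_hat), "voxel count mismatch with fit")
  stand_mean <- matrix(fit$alpha_hat, n, V, byrow = TRUE)
  if (!is.null(design) && nrow(fit$beta_hat) > 0) {
    stand_mean <- stand_mean + as.matrix(design) %*% fit$beta_hat
  }
  sp <- matrix(sqrt(fit$var_pooled), n, V, byrow = TRUE)
  Z <- (data - stand_mean) / sp
  ib <- as.integer(batch)
  Zadj <- (Z - fit$gamma_star[ib, , drop = FALSE]) /
    sqrt(fit$delta_star[ib, , drop = FALSE])
  out <- Zadj * sp + stand_mean
  if (length(fit$zero_var)) out[, fit$zero_var] <- data[, fit$zero_var]
  dimnames(out) <- dimnames(data)
  out
}

#' Fit and apply ComBat in one step
#'
#' @inheritParams combat_fit
#' @return harmonized matrix with the fit attached as attribute `"fit"`.
#' @export
combat_harmonize <- function(data, batch, design = NULL, tol = 1e-4) {
  fit <- combat_fit(data, batch, design, tol)
  out <- combat_apply(data, fit)
  attr(out, "fit") <- fit
  out
}
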