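# Independent brute-force oracles: direct loops over the metric
# definitions, kept deliberately naive and separate from the package
# implementations they check.

oracle_fisher_z <- function(r, clip = 1 - 1e-7) {
  atanh(max(min(r, clip), -clip))
}

# 4D array helpers ------------------------------------------------------
tiny_bold <- function(dims = c(6L, 6L, 4L), Tt = 40L, tr = 2,
                      voxel_size = 3, seed = 1L, mask = NULL) {
  set.seed(seed)
  arr <- array(rnorm(prod(dims) * Tt), c(dims, Tt))
  if (is.null(mask)) mask <- rep(TRUE, prod(dims))
  bold_image(arr, dims, voxel_size, tr, mask = mask)
}

oracle_seed_ifc <- function(bold, seed_voxels) {
  s <- rowMeans(bold$data[, seed_voxels, drop = FALSE])
  vals <- numeric(prod(bold$dims))
  for (v in which(bold$mask)) {
    vals[v] <- oracle_fisher_z(cor(bold$data[, v], s))
  }
  vals
}

oracle_vmhc <- function(bold) {
  dims <- bold$dims
  nx <- dims[1L]
  vals <- numeric(prod(dims))
  for (v in which(bold$mask)) {
    i <- (v - 1L) %% nx + 1L
    mv <- v + (nx + 1L - 2L * i)
    if (!bold$mask[mv]) next
    vals[v] <- oracle_fisher_z(cor(bold$data[, v], bold$data[, mv]))
  }
  vals
}

oracle_kendall_w <- function(series) {
  n <- nrow(series); K <- ncol(series)
  R <- apply(series, 2L, rank)
  Ri <- rowSums(R)
  S <- sum((Ri - K * (n + 1) / 2)^2)
  Tj <- 0
  for (j in seq_len(K)) {
    tt <- table(series[, j])
    Tj <- Tj + sum(tt^3 - tt)
  }
  12 * S / (K^2 * (n^3 - n) - K * Tj)
}

oracle_reho <- function(bold, neighborhood = 27L) {
  dims <- bold$dims
  vals <- numeric(prod(dims))
  conn_ord <- c("7" = 1L, "19" = 2L, "27" = 3L)[as.character(neighborhood)]
  for (v in which(bold$mask)) {
    v0 <- v - 1L
    i <- v0 %% dims[1L] + 1L
    j <- (v0 %/% dims[1L]) %% dims[2L] + 1L
    k <- v0 %/% (dims[1L] * dims[2L]) + 1L
    nb <- integer(0)
    for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
      if (sum(abs(c(di, dj, dk))) > conn_ord && !(di == 0 && dj == 0 && dk == 0)) next
      ni <- i + di; nj <- j + dj; nk <- k + dk
      if (ni < 1 || ni > dims[1L] || nj < 1 || nj > dims[2L] ||
          nk < 1 || nk > dims[3L]) next
      u <- (ni - 1L) + (nj - 1L) * dims[1L] +
        (nk - 1L) * dims[1L] * dims[2L] + 1L
      if (bold$mask[u]) nb <- c(nb, u)
    }
    if (length(nb) - 1L < 4L) next
    vals[v] <- oracle_kendall_w(bold$data[, nb, drop = FALSE])
  }
  vals
}

oracle_dc <- function(bold, r_threshold = 0.25, binarize = TRUE) {
  vox <- which(bold$mask)
  vals <- numeric(prod(bold$dims))
  for (a in seq_along(vox)) {
    acc <- 0
    for (b in seq_along(vox)) {
      if (a == b) next
      r <- cor(bold$data[, vox[a]], bold$data[, vox[b]])
      if (r > r_threshold) acc <- acc + if (binarize) 1 else r
    }
    vals[vox[a]] <- acc
  }
  vals
}

oracle_falff <- function(bold, band = c(0.01, 0.1)) {
  Tt <- nrow(bold$data)
  kmax <- floor(Tt / 2)
  freq <- (1:kmax) / (Tt * bold$tr)
  vals <- numeric(prod(bold$dims))
  for (v in which(bold$mask)) {
    amp <- Mod(fft(bold$data[, v]))[2:(kmax + 1L)]
    vals[v] <- sum(amp[freq >= band[1L] & freq <= band[2L]]) / sum(amp)
  }
  vals
}

# Type-III eta_p^2 by explicit projection matrices ----------------------
oracle_type3_eta <- function(y, X_full, term_cols) {
  P <- function(X) X %*% solve(crossprod(X)) %*% t(X)
  Pf <- P(X_full)
  ss_err <- sum((y - Pf %*% y)^2)
  Xr <- X_full[, -term_cols, drop = FALSE]
  Pr <- P(Xr)
  ss_term <- sum((Pf %*% y - Pr %*% y)^2)
  n <- length(y); p <- ncol(X_full)
  df1 <- length(term_cols); df2 <- n - p
  Fv <- (ss_term / df1) / (ss_err / df2)
  list(eta = ss_term / (ss_term + ss_err), F = Fv, df1 = df1, df2 = df2)
}

# 3D connected components by breadth-first search -----------------------
oracle_components <- function(voxels, dims, connectivity = 26L) {
  conn_ord <- c("6" = 1L, "18" = 2L, "26" = 3L)[as.character(connectivity)]
  inset <- logical(prod(dims)); inset[voxels] <- TRUE
  lab <- integer(length(voxels)); names(lab) <- voxels
  cur <- 0L
  for (v in voxels) {
    if (lab[as.character(v)] > 0L) next
    cur <- cur + 1L
    queue <- v
    lab[as.character(v)] <- cur
    while (length(queue)) {
      w <- queue[1L]; queue <- queue[-1L]
      w0 <- w - 1L
      i <- w0 %% dims[1L] + 1L
      j <- (w0 %/% dims[1L]) %% dims[2L] + 1L
      k <- w0 %/% (dims[1L] * dims[2L]) + 1L
      for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
        if (di == 0 && dj == 0 && dk == 0) next
        if (sum(abs(c(di, dj, dk))) > conn_ord) next
        ni <- i + di; nj <- j + dj; nk <- k + dk
        if (ni < 1 || ni > dims[1L] || nj < 1 || nj > dims[2L] ||
            nk < 1 || nk > dims[3L]) next
        u <- (ni - 1L) + (nj - 1L) * dims[1L] +
          (nk - 1L) * dims[1L] * dims[2L] + 1L
        if (inset[u] && lab[as.character(u)] == 0L) {
          lab[as.character(u)] <- cur
          queue <- c(queue, u)
        }
      }
    }
  }
  unname(lab)
}

# small phenotype table builder -----------------------------------------
make_pheno <- function(n_per_cell = 10L, n_sites = 2L, seed = 1L) {
  set.seed(seed)
  g <- expand.grid(site = paste0("site", seq_len(n_sites)),
                   dx = c("NT", "ASD"), sex = c("M", "F"),
                   rep = seq_len(n_per_cell), stringsAsFactors = FALSE)
  data.frame(subject_id = sprintf("s%04d", seq_len(nrow(g))),
             site = g$site,
             dx = factor(g$dx, levels = c("NT", "ASD")),
             sex = factor(g$sex, levels = c("M", "F")),
             age = runif(nrow(g), 7, 18),
             fiq = rnorm(nrow(g), 100, 10),
             mfd = exp(rnorm(nrow(g), log(0.1), 0.3)),
             stringsAsFactors = FALSE)
}
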