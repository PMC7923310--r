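test_that("seed connectivity matches the closed-form Fisher z cases", {
  b <- tiny_bold(c(4L, 4L, 2L), Tt = 30L, seed = 1L)
  seedv <- 1:2
  s <- rowMeans(b$data[, seedv])
  b$data[, 5L] <- s                               # identical to seed mean
  resid <- residuals(lm(b$data[, 6L] ~ s))
  b$data[, 6L] <- resid                           # orthogonal to seed
  m <- seed_ifc(b, seedv)
  expect_equal(m$values[5L], atanh(1 - 1e-7))
  expect_lt(abs(m$values[6L]), 1e-10)
  ## exact r = 0.5: y = 0.5 xs + sqrt(0.75) es with xs, es orthonormal
  x <- c(-1, 0, 1, 2, -2, 0.5, -0.5, 1.5, -1.5, 0)
  set.seed(2)
  e <- residuals(lm(rnorm(10L) ~ x))
  xs <- as.numeric(scale(x)); es <- as.numeric(scale(e))
  y <- 0.5 * xs + sqrt(0.75) * es
  b2 <- bold_image(cbind(x, y, matrix(rnorm(80L), 10L)), c(10L, 1L, 1L), 3, 2)
  m2 <- seed_ifc(b2, 1L)
  expect_equal(m2$values[2L], atanh(0.5), tolerance = 1e-12)
  expect_equal(atanh(0.5), 0.5493, tolerance = 1e-4)
  bz <- b; bz$data[, seedv] <- 1
  expect_error(seed_ifc(bz, seedv), "zero-variance seed")
})

test_that("vmhc is exactly mirror symmetric and clips perfect correlation", {
  b <- tiny_bold(c(6L, 4L, 3L), Tt = 25L, seed = 3L)
  ## force mirror symmetry: copy left half onto right half
  dims <- b$dims
  idx <- seq_len(prod(dims))
  i <- (idx - 1L) %% 6L + 1L
  mirror <- idx + (7L - 2L * i)
  left <- idx[i <= 3L]
  b$data[, mirror[left]] <- b$data[, left]
  m <- vmhc(b)
  expect_equal(unique(m$values[m$mask]), atanh(1 - 1e-7))
  ## symmetry holds for arbitrary data too
  b2 <- tiny_bold(c(6L, 4L, 3L), Tt = 25L, seed = 4L)
  m2 <- vmhc(b2)
  expect_identical(m2$values, m2$values[mirror])
  ## independent hemispheres average near zero
  big <- tiny_bold(c(10L, 8L, 6L), Tt = 60L, seed = 5L)
  m3 <- vmhc(big)
  expect_lt(abs(mean(m3$values[m3$mask])), 0.02)
})

test_that("kendall_w reproduces hand-computed and boundary cases", {
  expect_equal(kendall_w(matrix(rep(sin(1:27), 27L), 27L)), 1)
  expect_equal(kendall_w(cbind(1:10, 10:1)), 0)
  ## K=3, n=3 with ranks (1,2,3),(1,2,3),(3,2,1): S = 2, W = 24/216
  w <- kendall_w(cbind(c(10, 20, 30), c(1, 2, 3), c(5, 4, 3)))
  expect_equal(w, 12 * 2 / (9 * 24), tolerance = 1e-12)
  expect_equal(w, oracle_kendall_w(cbind(c(10, 20, 30), c(1, 2, 3),
                                         c(5, 4, 3))))
  expect_error(kendall_w(matrix(1, 5L, 3L)), "zero denominator")
  expect_error(kendall_w(cbind(1:2, 2:1)), "3 timepoints")
})

test_that("reho has the documented neighborhood and edge rules", {
  b <- tiny_bold(c(6L, 6L, 4L), Tt = 30L, seed = 6L)
  m <- reho(b)
  ## interior voxel value equals a direct kendall_w over its 27 neighbors
  dims <- b$dims
  center <- 3L + 2L * 6L + 1L * 36L + 1L          # voxel (4, 3, 2)
  nb <- c()
  for (dk in -1:1) for (dj in -1:1) for (di in -1:1) {
    nb <- c(nb, center + di + dj * 6L + dk * 36L)
  }
  expect_equal(m$values[center], kendall_w(b$data[, nb]),
               tolerance = 1e-12)
  ## corner voxel has 7 available neighbors at 27-connectivity: computed
  ## with the reduced K and flagged
  corner <- 1L
  expect_true(corner %in% m$flags)
  expect_gt(m$values[corner], 0)
  ## masked voxel with too few neighbors is zeroed and flagged
  mask <- rep(FALSE, prod(dims)); mask[c(1L, prod(dims))] <- TRUE
  b2 <- tiny_bold(c(6L, 6L, 4L), Tt = 30L, seed = 7L, mask = mask)
  m2 <- reho(b2)
  expect_equal(m2$values[1L], 0)
  expect_true(1L %in% m2$flags)
  expect_error(reho(b, neighborhood = 9L), "neighborhood")
})

test_that("reho of iid noise averages 1/K and concordant signal gives W near 1", {
  b <- tiny_bold(c(8L, 8L, 5L), Tt = 120L, seed = 8L)
  m <- reho(b)
  interior <- setdiff(which(b$mask), m$flags)
  expect_lt(abs(mean(m$values[interior]) - 1 / 27), 0.005)
  ## common signal with distinct tiny jitter: W near 1 in the interior
  sig <- sin(seq_len(120L) / 5)
  b2 <- b
  b2$data <- matrix(sig, 120L, prod(b$dims)) +
    1e-6 * matrix(rnorm(120L * prod(b$dims)), 120L)
  m2 <- reho(b2)
  expect_gt(min(m2$values[interior]), 0.999)
})

test_that("degree centrality matches its definition in edge cases", {
  dims <- c(4L, 3L, 2L)
  sig <- rnorm(40L)
  b <- bold_image(matrix(sig, 40L, prod(dims)), dims, 3, 2)
  m <- degree_centrality(b)
  expect_true(all(m$values == prod(dims) - 1L))
  b2 <- tiny_bold(c(5L, 4L, 3L), Tt = 120L, seed = 9L)
  m2 <- degree_centrality(b2, r_threshold = 0.999)
  expect_true(all(m2$values == 0))
  ## analytic null mean degree at threshold 0.25, pooled over 3 volumes
  Tt <- 120L
  tcrit <- 0.25 * sqrt((Tt - 2) / (1 - 0.25^2))
  p_null <- pt(tcrit, Tt - 2, lower.tail = FALSE)
  mds <- sapply(20:22, function(s) {
    mean(degree_centrality(tiny_bold(c(8L, 8L, 4L), Tt = Tt,
                                     seed = s))$values)
  })
  n <- prod(c(8L, 8L, 4L))
  expect_lt(abs(mean(mds) - (n - 1) * p_null) / ((n - 1) * p_null), 0.15)
  ## weighted degrees are bounded by binarized degrees
  m4 <- degree_centrality(b2, binarize = FALSE)
  expect_true(all(m4$values <= degree_centrality(b2)$values + 1e-9))
})

test_that("falff matches sinusoid limits", {
  Tt <- 200L; tr <- 2
  t <- seq_len(Tt) * tr
  dat <- cbind(sin(2 * pi * 0.05 * t), sin(2 * pi * 0.2 * t))
  b <- bold_image(dat, c(2L, 1L, 1L), 3, tr)
  m <- falff(b)
  expect_gt(m$values[1L], 0.99)
  expect_lt(m$values[2L], 0.01)
  set.seed(11)
  bw <- bold_image(matrix(rnorm(Tt * 100L), Tt), c(10L, 10L, 1L), 3, tr)
  mw <- falff(bw)
  expect_true(all(mw$values >= 0 & mw$values <= 1))
})

test_that("all five metrics match brute-force oracles on a random volume", {
  b <- tiny_bold(c(6L, 6L, 4L), Tt = 40L, seed = 12L)
  seedv <- c(1L, 2L, 7L)
  expect_lt(max(abs(seed_ifc(b, seedv)$values - oracle_seed_ifc(b, seedv))),
            1e-10)
  expect_lt(max(abs(vmhc(b)$values - oracle_vmhc(b))), 1e-10)
  r_pkg <- reho(b)
  r_orc <- oracle_reho(b)
  expect_lt(max(abs(r_pkg$values - r_orc)), 1e-10)
  expect_lt(max(abs(degree_centrality(b)$values - oracle_dc(b))), 1e-10)
  expect_lt(max(abs(falff(b)$values - oracle_falff(b))), 1e-10)
})

test_that("metrics are invariant to global positive rescaling", {
  b <- tiny_bold(c(6L, 4L, 4L), Tt = 40L, seed = 13L)
  b2 <- b; b2$data <- b$data * 7.3
  expect_equal(vmhc(b2)$values, vmhc(b)$values, tolerance = 1e-10)
  expect_equal(reho(b2)$values, reho(b)$values, tolerance = 1e-10)
  expect_equal(falff(b2)$values, falff(b)$values, tolerance = 1e-10)
  expect_equal(degree_centrality(b2)$values, degree_centrality(b)$values)
  expect_equal(seed_ifc(b2, 1:2)$values, seed_ifc(b, 1:2)$values,
               tolerance = 1e-10)
})

test_that("standardize_map z-scores amplitude metrics and is affine invariant", {
  b <- tiny_bold(c(6L, 4L, 4L), Tt = 40L, seed = 14L)
  m <- reho(b)
  z <- standardize_map(m)
  expect_lt(abs(mean(z$values[z$mask])), 1e-10)
  expect_equal(sd(z$values[z$mask]), 1, tolerance = 1e-10)
  expect_equal(z$standardization, "zscore")
  m2 <- m; m2$values[m2$mask] <- 3 * m$values[m$mask] + 5
  expect_equal(standardize_map(m2)$values, z$values, tolerance = 1e-10)
  mc <- m; mc$values[mc$mask] <- 1
  expect_error(standardize_map(mc), "zero variance")
  ## Fisher-z maps pass through
  v <- vmhc(b)
  expect_identical(standardize_map(v), v)
})
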