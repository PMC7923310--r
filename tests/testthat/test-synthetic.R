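test_that("phenotype generation gives exact cell counts and is reproducible", {
  spec <- cohort_spec(n_sites = 2L, cell_sizes = c(5L, 5L, 5L, 5L),
                      rng_seed = 11L)
  tab <- generate_phenotypes(spec)
  expect_equal(nrow(tab), 40L)
  counts <- table(tab$dx, tab$sex)
  expect_true(all(counts == 10L))
  expect_true(all(table(tab$site) == 20L))
  expect_identical(tab, generate_phenotypes(spec))
  expect_true(all(tab$age >= 7 & tab$age <= 18))
})

test_that("group FIQ means are recovered at large n", {
  spec <- cohort_spec(n_sites = 1L, cell_sizes = c(200L, 200L, 200L, 200L),
                      rng_seed = 3L)
  tab <- generate_phenotypes(spec)
  expect_lt(abs(mean(tab$fiq[tab$dx == "ASD"]) - 106), 2)
  expect_lt(abs(mean(tab$fiq[tab$dx == "NT"]) - 112), 2)
})

test_that("motion traces hit the target mean FD and degenerate cleanly", {
  set.seed(5)
  for (target in c(0.08, 0.15, 0.3)) {
    mot <- generate_motion(150L, target)
    mfd <- mean(framewise_displacement(mot))
    expect_lt(abs(mfd - target) / target, 0.2)
  }
  z <- generate_motion(100L, 0)
  expect_true(all(z == 0))
  expect_equal(framewise_displacement(z), rep(0, 99L))
  set.seed(9); a <- generate_motion(60L, 0.1)
  set.seed(9); b <- generate_motion(60L, 0.1)
  expect_identical(a, b)
  expect_error(generate_motion(1L, 0.1), "2 timepoints")
})

test_that("noise-free homotopic coupling gives perfect mirror correlation", {
  spec <- cohort_spec(n_sites = 1L, cell_sizes = c(1L, 0L, 0L, 0L),
                      grid_dims = c(8L, 8L, 6L), n_timepoints = 50L)
  tab <- generate_phenotypes(spec)
  eff <- effect_spec(base_coupling = 1)
  b <- generate_bold(tab[1L, ], spec, eff, seed = 2L)
  v <- vmhc(b)
  expect_equal(unique(round(v$values[v$mask], 6)),
               round(atanh(1 - 1e-7), 6))
})

test_that("generated BOLD is reproducible and rejects bad ROIs", {
  spec <- cohort_spec(n_sites = 1L, cell_sizes = c(1L, 0L, 0L, 0L),
                      grid_dims = c(8L, 8L, 6L), n_timepoints = 40L)
  tab <- generate_phenotypes(spec)
  b1 <- generate_bold(tab[1L, ], spec, seed = 7L)
  b2 <- generate_bold(tab[1L, ], spec, seed = 7L)
  expect_identical(b1$data, b2$data)
  out_roi <- which(!ellipsoid_mask(spec$grid_dims))[1L]
  bad <- effect_spec(list(list(channel = "vmhc", roi = out_roi, base = 0.5,
                               beta_dx = 0, beta_sex = 0, beta_int = 0)))
  expect_error(generate_bold(tab[1L, ], spec, bad, seed = 1L),
               "outside the brain mask")
  expect_error(effect_spec(list(list(channel = "vmhc", roi = 1L, base = 0.9,
                                     beta_dx = 0.3, beta_sex = 0,
                                     beta_int = 0))),
               "\\[0, 1\\]")
})

test_that("negative interaction on homotopic coupling yields the
           NT-F-highest / ASD-F-lowest cell ordering", {
  dims <- c(10L, 10L, 8L)
  spec <- cohort_spec(n_sites = 1L, cell_sizes = c(40L, 40L, 40L, 40L),
                      grid_dims = dims, n_timepoints = 60L, rng_seed = 21L)
  tab <- generate_phenotypes(spec)
  roi_l <- roi_box(dims, c(3L, 4L), c(4L, 6L), c(4L, 5L))
  roi <- sort(c(roi_l, mirror_voxels(roi_l, dims)))
  eff <- effect_spec(list(list(channel = "vmhc", roi = roi, base = 0.30,
                               beta_dx = 0, beta_sex = 0.06,
                               beta_int = -0.28)))
  cellmean <- sapply(seq_len(nrow(tab)), function(i) {
    b <- generate_bold(tab[i, ], spec, eff, seed = 100L + i)
    mean(vmhc(b)$values[roi])
  })
  cm <- tapply(cellmean, interaction(tab$dx, tab$sex), mean)
  expect_equal(names(which.max(cm)), "NT.F")
  expect_equal(names(which.min(cm)), "ASD.F")
})

test_that("site gamma on the coupling link scale shifts metric site means", {
  dims <- c(10L, 10L, 8L)
  spec <- cohort_spec(n_sites = 2L, cell_sizes = c(4L, 4L, 4L, 4L),
                      grid_dims = dims, n_timepoints = 120L, rng_seed = 31L)
  tab <- generate_phenotypes(spec)
  st <- site_spec(gamma = c(0.5, -0.5), delta = c(1, 1),
                  motion_shift = c(0, 0))
  eff <- effect_spec(base_coupling = 0.3)
  mm <- sapply(seq_len(nrow(tab)), function(i) {
    s <- match(tab$site[i], st$site)
    b <- generate_bold(tab[i, ], spec, eff, site = st[s, ], seed = 40L + i)
    mean(vmhc(b)$values[b$mask])
  })
  diff_sites <- mean(mm[tab$site == "site1"]) - mean(mm[tab$site == "site2"])
  expect_lt(abs(diff_sites - 1.0), 0.15)
})

test_that("behavior scores hit within-sex correlation targets and ranges", {
  tab <- make_pheno(n_per_cell = 150L, n_sites = 1L, seed = 13L)
  set.seed(17)
  ## the +-0.1 target band is on the expected realized correlation; a
  ## single draw at n=150 has sd ~0.075, so average three draws
  rF <- rM <- numeric(3L)
  for (r in 1:3) {
    sig <- rnorm(nrow(tab))
    out <- generate_behavior(tab, sig, behavior_spec(r_female = -0.3,
                                                     r_male = 0))
    asd <- out$dx == "ASD"
    rF[r] <- cor(sig[asd & out$sex == "F"], out$ados_sa[asd & out$sex == "F"])
    rM[r] <- cor(sig[asd & out$sex == "M"], out$ados_sa[asd & out$sex == "M"])
  }
  expect_true(all(is.na(out$ados_sa[out$dx == "NT"])))
  asd <- out$dx == "ASD"
  expect_true(all(out$ados_sa[asd] >= 1 & out$ados_sa[asd] <= 10))
  expect_true(all(out$ados_sa[asd] == round(out$ados_sa[asd])))
  expect_true(mean(rF) > -0.4 && mean(rF) < -0.2)
  expect_true(abs(mean(rM)) < 0.1)
  expect_true(all(out$ados_module[asd] %in% 2:4))
})

test_that("injected interaction magnitude is monotonically recovered", {
  dims <- c(10L, 10L, 8L)
  spec <- cohort_spec(n_sites = 1L, cell_sizes = c(10L, 10L, 10L, 10L),
                      grid_dims = dims, n_timepoints = 60L, rng_seed = 51L)
  tab <- generate_phenotypes(spec)
  roi_l <- roi_box(dims, c(3L, 4L), c(4L, 6L), c(4L, 5L))
  roi <- sort(c(roi_l, mirror_voxels(roi_l, dims)))
  betas <- c(0, 0.07, 0.14, 0.21, 0.28)
  reps <- 6L
  res <- expand.grid(beta = betas, rep = seq_len(reps))
  res$eta <- NA_real_
  for (rr in seq_len(nrow(res))) {
    eff <- effect_spec(list(list(channel = "vmhc", roi = roi, base = 0.30,
                                 beta_dx = 0, beta_sex = 0,
                                 beta_int = -res$beta[rr])))
    mns <- sapply(seq_len(nrow(tab)), function(i) {
      b <- generate_bold(tab[i, ], spec, eff,
                         seed = 1000L * rr + i)
      mean(vmhc(b)$values[roi])
    })
    ef <- full_model_effects(mns, tab)
    res$eta[rr] <- ef$eta_p_sq[ef$term == "dx_by_sex"]
  }
  expect_gt(cor(res$beta, res$eta, method = "spearman"), 0.9)
})
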