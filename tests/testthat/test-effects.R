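test_that("cluster means are exact for degenerate masks", {
  maps <- matrix(1:12, 3L, 4L)
  expect_equal(extract_cluster_means(maps, 2L), maps[, 2L])
  cmap <- matrix(7.5, 3L, 4L)
  expect_equal(extract_cluster_means(cmap, 1:4), rep(7.5, 3L))
  chk <- matrix(rep(c(1, 3), each = 3L), 3L)     # checkerboard a/b
  expect_equal(extract_cluster_means(chk, 1:2), rep(2, 3L))
  expect_error(extract_cluster_means(maps, integer(0)), "empty")
})

test_that("eta_p^2 matches the F/df conversion identity", {
  expect_equal(f_to_eta_sq(4.44, 1, 311), 4.44 / (4.44 + 311),
               tolerance = 1e-12)
  expect_equal(round(f_to_eta_sq(4.44, 1, 311), 4), 0.0141)
  set.seed(1)
  for (r in 1:5) {
    Fv <- runif(1, 0.1, 20); d1 <- sample(1:4, 1L); d2 <- sample(20:300, 1L)
    ss_e <- runif(1, 1, 10)
    ss_t <- Fv * d1 * ss_e / d2
    expect_equal(ss_t / (ss_t + ss_e), f_to_eta_sq(Fv, d1, d2),
                 tolerance = 1e-10)
  }
})

test_that("full-model effects agree with a projection-matrix oracle", {
  set.seed(2)
  tab <- make_pheno(n_per_cell = 12L)
  y <- rnorm(nrow(tab)) + 0.6 * (tab$dx == "ASD") * (tab$sex == "F")
  ef <- full_model_effects(y, tab)
  ## oracle: type-III via sum-to-zero coded projections
  dxs <- ifelse(tab$dx == "ASD", 1, -1)
  sxs <- ifelse(tab$sex == "F", 1, -1)
  Xf <- cbind(1, dxs, sxs, dxs * sxs, tab$age - mean(tab$age),
              tab$mfd - mean(tab$mfd))
  for (tm in list(c("dx", 2L), c("sex", 3L), c("dx_by_sex", 4L))) {
    orc <- oracle_type3_eta(y, Xf, as.integer(tm[2L]))
    row <- ef[ef$term == tm[1L], ]
    expect_equal(row$eta_p_sq, orc$eta, tolerance = 1e-10)
    expect_equal(row$F, orc$F, tolerance = 1e-8)
    expect_equal(row$df2, orc$df2)
  }
  expect_true(all(ef$ci_lo <= ef$eta_p_sq + 1e-12))
  expect_true(all(ef$ci_hi >= ef$eta_p_sq - 1e-12))
})

test_that("type-III F statistics agree with the car reference", {
  skip_if_not_installed("car")
  set.seed(7)
  tab <- make_pheno(n_per_cell = 9L)
  tab <- tab[-c(1L, 5L, 8L), ]                    # unbalanced cells
  y <- rnorm(nrow(tab)) + 0.4 * (tab$dx == "ASD")
  ef <- full_model_effects(y, tab)
  fit <- lm(y ~ dx * sex + I(age - mean(age)) + I(mfd - mean(mfd)),
            data = cbind(tab, y = y),
            contrasts = list(dx = "contr.sum", sex = "contr.sum"))
  a3 <- car::Anova(fit, type = 3)
  for (tm in list(c("dx", "dx"), c("sex", "sex"), c("dx_by_sex", "dx:sex"))) {
    expect_equal(ef$F[ef$term == tm[1L]], a3[tm[2L], "F value"],
                 tolerance = 1e-8)
  }
})

test_that("noise-free generating terms give eta of 1 and correct directions", {
  tab <- make_pheno(n_per_cell = 8L)
  y <- 2 * as.integer(tab$dx == "ASD")            # pure diagnosis effect
  ef <- full_model_effects(y, tab, covariates = character(0))
  expect_equal(ef$eta_p_sq[ef$term == "dx"], 1, tolerance = 1e-10)
  expect_equal(ef$direction[ef$term == "dx"], 1)  # ASD > NT
  y2 <- -1.5 * as.integer(tab$sex == "F")
  ef2 <- full_model_effects(y2, tab, covariates = character(0))
  expect_equal(ef2$direction[ef2$term == "sex"], -1)
  ## adjusted cell means reproduce the raw cell means without covariates
  expect_equal(ef$mean_asd_m[1L] - ef$mean_nt_m[1L], 2, tolerance = 1e-10)
})

test_that("null simulations put the eta CI lower bound at zero", {
  set.seed(3)
  tab <- make_pheno(n_per_cell = 25L)
  lows <- replicate(30L, {
    ef <- full_model_effects(rnorm(nrow(tab)), tab)
    ef$ci_lo[ef$term == "dx"]
  })
  expect_gt(mean(lows == 0), 0.6)
})

test_that("residualization is orthogonal, variance-reducing and centered", {
  set.seed(4)
  tab <- make_pheno(n_per_cell = 10L)
  y <- rnorm(nrow(tab)) + 0.2 * tab$age
  r <- residualize(y, tab, terms = c("dx", "sex", "dx_by_sex", "age", "mfd"))
  expect_lt(abs(mean(r)), 1e-10)
  expect_lt(abs(sum(r * tab$age)), 1e-8)
  expect_lt(abs(sum(r * (tab$dx == "ASD"))), 1e-8)
  expect_lte(var(r), var(y))
  ## already-orthogonal input: residual is just the centered input
  yo <- residualize(y, tab, terms = c("age", "mfd"))
  expect_equal(residualize(yo, tab, terms = c("age", "mfd")), yo,
               tolerance = 1e-10)
})

test_that("replication classification implements the direction + 0.01 rule", {
  disc <- data.frame(term = "dx_by_sex", direction = -1, eta_p_sq = 0.05)
  repl <- function(dir, eta) {
    data.frame(term = "dx_by_sex", direction = dir, eta_p_sq = eta)
  }
  expect_equal(classify_replication(disc, repl(-1, 0.02)), "R+")
  expect_equal(classify_replication(disc, repl(-1, 0.005)), "R-")
  expect_equal(classify_replication(disc, repl(1, 0.05)), "R-")
  expect_equal(classify_replication(disc, repl(-1, 0.01)), "R+")  # boundary
  expect_error(classify_replication(disc,
    data.frame(term = "dx", direction = -1, eta_p_sq = 0.05)), "mismatch")
})

test_that("effects and classification are invariant to positive affine maps", {
  set.seed(5)
  tab <- make_pheno(n_per_cell = 15L)
  y <- rnorm(nrow(tab)) +
    0.5 * as.integer(tab$dx == "ASD") * as.integer(tab$sex == "F")
  e1 <- full_model_effects(y, tab)
  e2 <- full_model_effects(4.2 * y + 11, tab)
  expect_equal(e1$eta_p_sq, e2$eta_p_sq, tolerance = 1e-10)
  expect_equal(e1$direction, e2$direction)
  expect_equal(classify_replication(e1, e2),
               classify_replication(e1, e1))
})

test_that("leave-one-site-out reports one row per site and full consistency
           for homogeneous effects", {
  set.seed(6)
  tab <- make_pheno(n_per_cell = 12L, n_sites = 4L)
  y <- rnorm(nrow(tab)) -
    1.0 * as.integer(tab$dx == "ASD") * as.integer(tab$sex == "F")
  ls <- loso_stability(y, tab, term = "dx_by_sex")
  expect_equal(nrow(ls$per_site), 4L)
  expect_equal(ls$sign_consistency, 1)
  expect_equal(unique(ls$per_site$direction), -1)
  tab2 <- make_pheno(n_per_cell = 10L, n_sites = 2L)
  expect_error(loso_stability(rnorm(nrow(tab2)), tab2), "3 sites")
})

test_that("ontology overlap returns one percentage per map", {
  dims <- c(6L, 6L, 4L)
  cl <- roi_box(dims, c(2L, 3L), c(2L, 3L), c(2L, 3L))
  maps <- c(
    list(as.numeric(seq_len(prod(dims)) %in% cl)),       # full cover
    list(numeric(prod(dims))),                           # disjoint
    replicate(10L, {
      m <- numeric(prod(dims)); m[sample(prod(dims), 30L)] <- 1; m
    }, simplify = FALSE))
  ov <- ontology_overlap(cl, maps)
  expect_length(ov, 12L)
  expect_equal(unname(ov[1L]), 100)
  expect_equal(unname(ov[2L]), 0)
  expect_true(all(ov >= 0 & ov <= 100))
  expect_error(ontology_overlap(integer(0), maps), "empty")
})
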