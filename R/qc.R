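#' Framewise displacement from 6-parameter motion traces
#'
#' Power-style backward differences: at each frame the FD is the sum of
#' absolute translation changes (mm) plus the head radius times the sum of
#' absolute rotation changes (rad), with a 50 mm radius by default.
#'
#' @param motion `T x 6` matrix: three translations (mm) then three
#'   rotations (rad).
#' @param radius head radius in mm converting rotations to arc length.
#' @return numeric vector of length `T - 1`; its mean is the subject's
#'   mean FD (mFD).
#' @export
framewise_displacement <- function(motion, radius = 50) {
  motion <- as.matrix(motion)
  .assert(nrow(motion) >= 2L, "need at least 2 timepoints")
  .assert(ncol(motion) == 6L, "motion must have 6 columns")
  .assert(all(is.finite(motion)), "non-finite motion parameters")
  d <- abs(diff(motion))
  rowSums(d[, 1:3, drop = FALSE]) + radius * rowSums(d[, 4:6, drop = FALSE])
}

#' Sample eligibility filter
#'
#' Retains subjects aged 7-18 years (inclusive), with full-scale IQ between
#' 70 and 148 (inclusive), and with mean framewise displacement no greater
#' than Q3 + 3 * IQR of the input sample's mFD distribution (type-7
#' quantiles).  The motion threshold is recomputed from each input sample
#' unless overridden.
#'
#' @param table phenotype table with columns `subject_id`, `age`, `fiq`,
#'   `mfd`.
#' @param age_range,fiq_range inclusive eligibility bounds.
#' @param mfd_threshold optional fixed mFD cut-off (mm); default computes
#'   Q3 + 3 * IQR from the sample.
#' @return list of class `eligibility_report`: `retained` (subject ids),
#'   `excluded` (data frame of ids and semicolon-joined reason codes from
#'   `age`, `fiq`, `mfd`), `mfd_threshold`, and `table` (retained rows).
#' @export
eligibility_filter <- function(table, age_range = c(7, 18),
                               fiq_range = c(70, 148),
                               mfd_threshold = NULL) {
  .assert(nrow(table) > 0, "empty phenotype table")
  need <- c("subject_id", "age", "fiq", "mfd")
  .assert(all(need %in% names(table)),
          paste("missing columns:",
                paste(setdiff(need, names(table)), collapse = ", ")))
  if (is.null(mfd_threshold)) {
    q <- quantile(table$mfd, c(0.25, 0.75), type = 7, names = FALSE)
    mfd_threshold <- q[2L] + 3 * (q[2L] - q[1L])
  }
  bad_age <- table$age < age_range[1L] | table$age > age_range[2L]
  bad_fiq <- table$fiq < fiq_range[1L] | table$fiq > fiq_range[2L]
  bad_mfd <- table$mfd > mfd_threshold
  reasons <- mapply(function(a, f, m) {
    paste(c("age", "fiq", "mfd")[c(a, f, m)], collapse = ";")
  }, bad_age, bad_fiq, bad_mfd)
  drop <- bad_age | bad_fiq | bad_mfd
  structure(list(
    retained = table$subject_id[!drop],
    excluded = data.frame(subject_id = table$subject_id[drop],
                          reason = reasons[drop],
                          stringsAsFactors = FALSE),
    mfd_threshold = mfd_threshold,
    table = table[!drop, , drop = FALSE]),
    class = "eligibility_report")
}

#' @export
print.eligibility_report <- function(x, ...) {
  cat("Eligibility: retained", length(x$retained), "excluded",
      nrow(x$excluded), sprintf("(mFD threshold %.3f mm)\n",
                                x$mfd_threshold))
  invisible(x)
}

#' Drop sites with underfilled diagnosis-by-sex cells
#'
#' Removes every site that has fewer than `min_n` subjects in any of the
#' four diagnosis-by-sex cells.
#'
#' @param table phenotype table with `site`, `dx`, `sex`.
#' @param min_n minimum per-cell count (default 3).
#' @return list: `table` (retained rows) and `dropped_sites`.
#' @export
site_cell_filter <- function(table, min_n = 3L) {
  .assert(nrow(table) > 0, "empty phenotype table")
  .assert(all(c("site", "dx", "sex") %in% names(table)),
          "site, dx, sex columns required")
  counts <- table(table$site, table$dx, table$sex)
  ok <- apply(counts, 1L, min) >= min_n
  dropped <- rownames(counts)[!ok]
  list(table = table[!(table$site %in% dropped), , drop = FALSE],
       dropped_sites = dropped)
}

#' Cohort summary with group comparison tests
#'
#' Per diagnosis-by-sex cell means, SDs and ranges of the continuous
#' phenotypes, with one-way ANOVA across the four cells for age and FIQ, a
#' Kruskal-Wallis test for mean FD (non-parametric, as motion distributions
#' are skewed), a chi-square test (no continuity correction) for
#' categorical columns, and two-sample t-tests comparing ASD males and
#' females on the ADOS scores.
#'
#' @param table phenotype table.
#' @return list of class `cohort_summary`: `cells` (per-cell descriptives),
#'   `tests` (data frame of statistic/df/p per variable), and `n`.
#' @export
cohort_summary <- function(table) {
  .assert(nrow(table) > 0, "empty phenotype table")
  cell <- droplevels(interaction(table$dx, table$sex, sep = "_"))
  .assert(nlevels(cell) >= 2L, "need at least 2 groups")
  num_vars <- intersect(c("age", "fiq", "mfd"), names(table))
  desc <- do.call(rbind, lapply(num_vars, function(v) {
    agg <- tapply(table[[v]], cell, function(x) {
      c(mean = mean(x), sd = sd(x), min = min(x), max = max(x))
    })
    out <- do.call(rbind, agg)
    data.frame(variable = v, cell = rownames(out), out, row.names = NULL)
  }))
  tests <- list()
  for (v in intersect(c("age", "fiq"), num_vars)) {
    if (all(tapply(table[[v]], cell, function(x) var(x) == 0 || length(x) < 2))) {
      tests[[v]] <- data.frame(variable = v, test = "anova",
                               statistic = NA_real_, df1 = NA_real_,
                               df2 = NA_real_, p = NA_real_,
                               note = "degenerate")
      next
    }
    fit <- aov(table[[v]] ~ cell)
    an <- anova(fit)
    tests[[v]] <- data.frame(variable = v, test = "anova",
                             statistic = an$`F value`[1L],
                             df1 = an$Df[1L], df2 = an$Df[2L],
                             p = an$`Pr(>F)`[1L], note = "")
  }
  if ("mfd" %in% num_vars) {
    kw <- kruskal.test(table$mfd, cell)
    tests$mfd <- data.frame(variable = "mfd", test = "kruskal",
                            statistic = unname(kw$statistic),
                            df1 = unname(kw$parameter), df2 = NA_real_,
                            p = kw$p.value, note = "")
  }
  if ("site" %in% names(table) && length(unique(table$site)) > 1L) {
    cs <- suppressWarnings(chisq.test(table(table$site, cell),
                                      correct = FALSE))
    tests$site <- data.frame(variable = "site", test = "chisq",
                             statistic = unname(cs$statistic),
                             df1 = unname(cs$parameter), df2 = NA_real_,
                             p = cs$p.value, note = "")
  }
  for (v in intersect(c("ados_css", "ados_sa", "ados_rrb"), names(table))) {
    asd <- table[table$dx == "ASD" & !is.na(table[[v]]), ]
    if (nrow(asd) >= 4L && nlevels(droplevels(asd$sex)) == 2L) {
      tt <- t.test(asd[[v]] ~ asd$sex)
      tests[[v]] <- data.frame(variable = v, test = "t_asd_m_vs_f",
                               statistic = unname(tt$statistic),
                               df1 = unname(tt$parameter), df2 = NA_real_,
                               p = tt$p.value, note = "")
    }
  }
  structure(list(cells = desc, tests = do.call(rbind, tests),
                 n = table(cell)), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort summary (n per cell):\n")
  print(x$n)
  cat("\nGroup tests:\n")
  print(x$tests, row.names = FALSE, digits = 4)
  invisible(x)
}
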