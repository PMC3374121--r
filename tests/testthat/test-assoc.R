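test_that("unadjusted allelic OR matches the 2x2 cross-product on published counts", {
  # counts reconstructed from a printed table: carriers 42 of 3,814 called
  # controls vs 20 of 3,992 called cases
  tc <- table_cohort(a_case_carrier = 20, b_ctrl_carrier = 42,
                     c_case_non = 3972, d_ctrl_non = 3772)
  a <- branch_association(tc$carriers, tc$records, "X", "overall",
                          no_covariates())
  cross <- (20 * 3772) / (42 * 3972)
  expect_equal(a$or_estimate, cross, tolerance = 1e-6)
  expect_lt(a$or_estimate, 1)       # protective direction
  expect_equal(a$maf_controls, 42 / 3814)
  expect_equal(a$maf_cases, 20 / 3992)
  expect_equal(a$method, "score")
})

test_that("equal carrier frequencies give a null score statistic and OR 1", {
  tc <- table_cohort(30, 30, 270, 270)
  a <- branch_association(tc$carriers, tc$records, "X", "overall",
                          no_covariates())
  expect_equal(a$score_stat, 0, tolerance = 1e-10)
  expect_equal(a$or_estimate, 1, tolerance = 1e-8)
})

test_that("with no covariates the score test equals Pearson chi-square", {
  set.seed(31)
  for (i in 1:60) {
    tab <- matrix(sample(1:60, 4, replace = TRUE), 2)
    tc <- table_cohort(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
    a <- branch_association(tc$carriers, tc$records, "X", "overall",
                            no_covariates())
    cs <- suppressWarnings(
      stats::chisq.test(tab, correct = FALSE)$statistic)
    expect_equal(a$score_stat, unname(cs), tolerance = 1e-8)
  }
})

test_that("the adjusted score statistic matches glm anova(test = 'Rao')", {
  cfg <- stage1_sim_config(effect_map = c("E1b1b1c" = 0.5), seed = 33L,
                           scale = 0.3)
  sim <- simulate_cohort(cfg)
  carr <- branch_status(apply_qc(sim$genotypes), cfg$tree)
  for (b in c("E1b1b1c", "I", "R1b1a2")) {
    a <- branch_association(carr, sim$records, b, "overall",
                            covariate_spec())
    idx <- match(carr$sample_ids, sim$records$sample_id)
    d <- data.frame(y = as.integer(sim$records$is_case[idx]),
                    x = carr$status[, b],
                    age_bin = cut(sim$records$age_years[idx],
                                  c(-Inf, 50, 60, 70, 80, Inf),
                                  right = FALSE),
                    study = factor(sim$records$study[idx]),
                    pc1 = sim$records$pc1[idx])
    d <- d[stats::complete.cases(d), ]
    fit <- glm(y ~ age_bin + study + pc1 + x, binomial, data = d)
    rao <- stats::anova(fit, test = "Rao")["x", "Rao"]
    expect_equal(a$score_stat, rao, tolerance = 1e-6, info = b)
  }
})

test_that("score statistic is invariant to covariate reference relevelling", {
  cfg <- stage1_sim_config(seed = 35L, scale = 0.15)
  sim <- simulate_cohort(cfg)
  carr <- branch_status(apply_qc(sim$genotypes), cfg$tree)
  a1 <- branch_association(carr, sim$records, "I1", "overall")
  rec2 <- sim$records
  rec2$study <- factor(rec2$study,
                       levels = rev(sort(unique(rec2$study))))
  a2 <- branch_association(carr, rec2, "I1", "overall")
  expect_equal(a1$score_stat, a2$score_stat, tolerance = 1e-9)
  expect_equal(a1$p_value, a2$p_value, tolerance = 1e-9)
})

test_that("null simulations keep the score test near nominal size", {
  # standalone quick check at modest n; the full-pipeline calibration run
  # lives in the acceptance suite
  set.seed(37)
  n <- 800; reps <- 300
  rej <- 0L
  for (r in seq_len(reps)) {
    tab <- table(factor(rbinom(n, 1, 0.2), 0:1),
                 factor(rbinom(n, 1, 0.5), 0:1))
    tc <- table_cohort(tab["1", "1"], tab["1", "0"],
                       tab["0", "1"], tab["0", "0"])
    a <- branch_association(tc$carriers, tc$records, "X", "overall",
                            no_covariates())
    rej <- rej + (a$p_value <= 0.05)
  }
  expect_gt(rej / reps, 0.02)
  expect_lt(rej / reps, 0.09)
})

test_that("zero carrier-case cells fall back to the Fisher exact route", {
  tc <- table_cohort(0, 8, 44, 228)
  a <- branch_association(tc$carriers, tc$records, "X", "overall",
                          no_covariates())
  expect_equal(a$method, "fisher")
  expect_equal(a$or_estimate, 0)
  expect_true(is.finite(a$ci_high) && a$ci_high > 0)
})

test_that("all-carrier and no-carrier branches are reported untestable", {
  tc <- table_cohort(10, 10, 0, 0)
  a <- branch_association(tc$carriers, tc$records, "X", "overall",
                          no_covariates())
  expect_equal(a$method, "untestable")
  expect_true(is.na(a$p_value))
})

test_that("empty covariate strata are dropped as in the published footnote", {
  # one study contributes controls only: its samples cannot inform the
  # carrier effect and the whole category is removed
  tc <- table_cohort(15, 20, 185, 180)
  rec <- tc$records
  rec$study[rec$is_case == FALSE][1:30] <- "CTRLONLY"
  a <- branch_association(tc$carriers, rec, "X", "overall",
                          covariate_spec(include_age = FALSE,
                                         include_pc1 = FALSE))
  expect_equal(a$n_dropped_strata, 1L)
  expect_equal(a$n_controls, 200L - 30L)
})

test_that("fisher_exact_or matches brute-force hypergeometric enumeration", {
  brute_p <- function(m) {
    x <- m[1, 1]; m1 <- sum(m[1, ]); m2 <- sum(m[2, ]); k <- sum(m[, 1])
    a <- max(0, k - m2):min(m1, k)
    pr <- dhyper(a, m1, m2, k)
    sum(pr[pr <= dhyper(x, m1, m2, k) * (1 + 1e-7)])
  }
  m <- matrix(c(1, 9, 11, 3), 2, byrow = TRUE)
  expect_equal(fisher_exact_or(m)$p_value, brute_p(m), tolerance = 1e-10)
  set.seed(41)
  for (i in 1:40) {
    m <- matrix(rpois(4, 6) + 1, 2)
    expect_equal(fisher_exact_or(m)$p_value, brute_p(m),
                 tolerance = 1e-10)
  }
  bal <- matrix(c(5, 5, 5, 5), 2)
  fb <- fisher_exact_or(bal)
  expect_equal(fb$p_value, 1)
  expect_equal(fb$or_estimate, 1, tolerance = 1e-6)
  expect_error(fisher_exact_or(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "margin")
})

test_that("case-group difference test behaves as a case-only score test", {
  # identical carrier frequency in both case groups -> p near 1
  n_half <- 300L
  calls <- matrix(rep(c("D", "A", "D", "A"),
                      c(30, n_half - 30, 30, n_half - 30)),
                  ncol = 1, dimnames = list(sprintf("s%04d", 1:(2 * n_half)),
                                            "M1"))
  tr <- haplo_tree_from_text(
    "node\tparent\tmarkers\nY\tROOT\t\nX\tY\tM1:A>G\n")
  gl <- rep(c(6L, 9L), each = n_half)
  stg <- rep(c(1L, 3L), each = n_half)
  co <- make_cohort(calls, is_case = rep(TRUE, 2 * n_half),
                    gleason = gl, stage = stg)
  carr <- branch_status(apply_qc(co$genotypes), tr)
  res <- case_group_difference(carr, co$records, "X", no_covariates())
  expect_equal(res$method, "score")
  expect_gt(res$p_value, 0.99)
  expect_equal(res$n_nonaggressive, n_half)
  expect_equal(res$n_aggressive, n_half)

  # with no covariates the case-only test is the Pearson chi-square
  calls2 <- calls
  calls2[331:360] <- "D"   # aggressive group: 60 carriers
  co2 <- make_cohort(calls2, is_case = rep(TRUE, 2 * n_half),
                     gleason = gl, stage = stg)
  carr2 <- branch_status(apply_qc(co2$genotypes), tr)
  res2 <- case_group_difference(carr2, co2$records, "X", no_covariates())
  tab <- matrix(c(60, 30, n_half - 60, n_half - 30), 2, byrow = TRUE)
  cs <- stats::chisq.test(tab, correct = FALSE)$statistic
  expect_equal(res2$score_stat, unname(cs), tolerance = 1e-8)
})

test_that("run_association stacks subgroups and annotates markers", {
  cfg <- stage1_sim_config(seed = 43L, scale = 0.1)
  sim <- simulate_cohort(cfg)
  carr <- branch_status(apply_qc(sim$genotypes), cfg$tree)
  res <- run_association(carr, sim$records,
                         branches = c("E1b1b1c", "N1c"),
                         tree = cfg$tree)
  expect_equal(nrow(res), 6L)
  expect_setequal(unique(res$subgroup),
                  c("overall", "nonaggressive", "aggressive"))
  expect_equal(res$locus[res$branch == "E1b1b1c"][1], "M123")
  expect_equal(res$alleles[res$branch == "N1c"][1], "T|C")
  # controls shared across subgroups; case groups partition the cases
  overall <- res[res$branch == "N1c" & res$subgroup == "overall", ]
  nonag <- res[res$branch == "N1c" & res$subgroup == "nonaggressive", ]
  expect_lt(nonag$n_cases, overall$n_cases)
})
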