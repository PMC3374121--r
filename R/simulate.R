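# Synthetic cohorts: tree-consistent haploid genotypes from per-study
# haplogroup frequency profiles, a logistic disease model, substructure
# clusters, and genotyping noise.

#' Define one study profile for the cohort simulator
#'
#' A profile fixes, for one study, the target case/control counts, the
#' haplogroup composition (a frequency vector over leaf classes — tree node
#' labels, internal nodes meaning the corresponding paragroup), the age
#' distribution, and the population-substructure mixture: a fraction of men
#' drawn from an Ashkenazi-Jewish-like cluster with its own haplogroup
#' frequencies and principal-component coordinates (EV1 < 0, EV2 > 0; the
#' main cluster is generated with EV1 > 0, so substructure classification
#' is exact on noiseless data).
#'
#' @param study Study label.
#' @param n_cases,n_controls Target sampled counts.
#' @param leaf_freqs Named numeric vector over tree node labels, summing to
#'   1 (tolerance 1e-6).
#' @param age_mean,age_sd,age_range Truncated-normal age parameters (years).
#' @param aj_fraction Fraction of men drawn from the AJ-like cluster.
#' @param aj_leaf_freqs Frequency vector for the AJ-like cluster (required
#'   when `aj_fraction > 0`).
#' @param baseline_shift Study-specific additive shift on the disease
#'   logit.
#' @return A `study_profile` list.
#' @export
study_profile <- function(study, n_cases, n_controls, leaf_freqs,
                          age_mean = 65, age_sd = 8,
                          age_range = c(45, 90),
                          aj_fraction = 0, aj_leaf_freqs = NULL,
                          baseline_shift = 0) {
  check_freq_vector(leaf_freqs, paste0("leaf_freqs (", study, ")"))
  if (aj_fraction < 0 || aj_fraction >= 1)
    stop("aj_fraction must be in [0, 1)")
  if (aj_fraction > 0) {
    if (is.null(aj_leaf_freqs))
      stop("aj_leaf_freqs required when aj_fraction > 0")
    check_freq_vector(aj_leaf_freqs, paste0("aj_leaf_freqs (", study, ")"))
  }
  structure(list(study = study, n_cases = n_cases, n_controls = n_controls,
                 leaf_freqs = leaf_freqs, age_mean = age_mean,
                 age_sd = age_sd, age_range = age_range,
                 aj_fraction = aj_fraction, aj_leaf_freqs = aj_leaf_freqs,
                 baseline_shift = baseline_shift),
            class = "study_profile")
}

check_freq_vector <- function(f, what) {
  if (is.null(names(f)) || any(names(f) == ""))
    stop(what, " must be fully named")
  if (any(f < 0)) stop(what, " has negative entries")
  if (abs(sum(f) - 1) > 1e-6)
    stop(what, " must sum to 1 (got ", format(sum(f)), ")")
  invisible(f)
}

#' Simulation configuration
#'
#' Couples a haplogroup tree with study profiles, branch disease effects
#' and error rates. Case status is generated prospectively: each man gets
#' a Bernoulli draw on the logistic scale
#' `baseline_logit + study shift + sum(log allelic OR over carried effect
#' branches) + age_log_or_per_decade * (age - 65)/10`, after which cases
#' and controls are subsampled to the profile's target counts (odds ratios
#' are preserved under such outcome-dependent sampling). Missingness and
#' spurious heterozygous calls are injected per call after genotypes are
#' laid down along the root-to-leaf path.
#'
#' @param tree A `haplo_tree`.
#' @param study_profiles List of [study_profile()] objects.
#' @param effect_map Named numeric vector of allelic odds ratios per branch
#'   label (unlisted branches have OR 1).
#' @param baseline_logit Global intercept of the disease model (default 0:
#'   a balanced superpopulation, convenient for case-control subsampling).
#' @param age_log_or_per_decade Log OR of disease per decade of age
#'   (default 0.35).
#' @param panel Marker names genotyped on the panel; default: every tree
#'   marker attached to a node, minus `panel_exclude`.
#' @param panel_exclude Markers deliberately left untyped (default: none
#'   beyond those absent from `panel`).
#' @param missing_rate,het_error_rate Per-call probabilities of a missing
#'   and of a spurious heterozygous call, in `[0, 1)`.
#' @param seed Integer seed; `simulate_cohort()` uses it by default so the
#'   same configuration always reproduces the same cohort.
#' @return A `sim_config` list.
#' @export
sim_config <- function(tree, study_profiles, effect_map = numeric(0),
                       baseline_logit = 0, age_log_or_per_decade = 0.35,
                       panel = NULL, panel_exclude = character(0),
                       missing_rate = 0, het_error_rate = 0, seed = 1L) {
  stopifnot(inherits(tree, "haplo_tree"))
  if (inherits(study_profiles, "study_profile"))
    study_profiles <- list(study_profiles)
  for (p in study_profiles) {
    stopifnot(inherits(p, "study_profile"))
    stray <- setdiff(names(p$leaf_freqs), names(tree$nodes))
    if (length(stray))
      stop("leaf class(es) not in tree: ", paste(stray, collapse = ", "))
    if (!is.null(p$aj_leaf_freqs)) {
      stray <- setdiff(names(p$aj_leaf_freqs), names(tree$nodes))
      if (length(stray))
        stop("AJ leaf class(es) not in tree: ",
             paste(stray, collapse = ", "))
    }
  }
  if (length(effect_map)) {
    stray <- setdiff(names(effect_map), names(tree$nodes))
    if (length(stray))
      stop("effect branch(es) not in tree: ", paste(stray, collapse = ", "))
    if (any(effect_map <= 0)) stop("allelic ORs must be positive")
  }
  if (missing_rate < 0 || missing_rate >= 1 ||
      het_error_rate < 0 || het_error_rate >= 1)
    stop("error rates must lie in [0, 1)")
  if (is.null(panel)) panel <- setdiff(tree$markers$name, panel_exclude)
  stray <- setdiff(panel, tree$markers$name)
  if (length(stray))
    stop("panel marker(s) not in tree: ", paste(stray, collapse = ", "))
  structure(list(tree = tree, study_profiles = study_profiles,
                 effect_map = effect_map, baseline_logit = baseline_logit,
                 age_log_or_per_decade = age_log_or_per_decade,
                 panel = panel, missing_rate = missing_rate,
                 het_error_rate = het_error_rate, seed = seed),
            class = "sim_config")
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  qnorm(runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd)), mean, sd)
}

#' Simulate a case-control cohort
#'
#' Draws, per study, a superpopulation of men (haplogroup leaf class from
#' the study's — or the AJ cluster's — frequency vector; age; substructure
#' coordinates), assigns case status by the logistic disease model, and
#' subsamples to the study's target case and control counts. Genotypes are
#' laid down tree-consistently (derived at every panel marker on the
#' root-to-class path, ancestral elsewhere), then missingness and spurious
#' heterozygous calls are injected. Fully reproducible from the seed.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed (default `config$seed`); `NULL` to continue
#'   from the current RNG state (used by [recovery_experiment()]).
#' @return List: `genotypes` (a raw `genotype_matrix` — run [apply_qc()]),
#'   `records` (phenotype data.frame as from [read_cohort()]), `truth`
#'   (per-sample data.frame: `sample_id`, `study`, `leaf`, `path`,
#'   `aj_cluster`, `linear_predictor`, `is_case`).
#' @export
simulate_cohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  tree <- config$tree
  panel <- config$panel

  # class -> carried branch indicator over panel markers
  classes <- unique(unlist(c(
    lapply(config$study_profiles, function(p) names(p$leaf_freqs)),
    lapply(config$study_profiles, function(p) names(p$aj_leaf_freqs)))))
  paths <- lapply(classes, function(cl) tree_path(tree, cl))
  names(paths) <- classes
  panel_node <- unname(tree$marker_index[panel])
  path_mat <- t(vapply(paths, function(pp) panel_node %in% pp,
                       logical(length(panel))))
  colnames(path_mat) <- panel
  effect_lp <- vapply(classes, function(cl) {
    on_path <- intersect(names(config$effect_map), paths[[cl]])
    sum(log(config$effect_map[on_path]))
  }, numeric(1))

  per_study <- lapply(config$study_profiles, function(prof) {
    draw_study(prof, config, classes, effect_lp)
  })
  cls <- unlist(lapply(per_study, `[[`, "class_idx"))
  n <- length(cls)

  calls <- matrix("A", n, length(panel))
  calls[path_mat[cls, , drop = FALSE]] <- "D"
  if (config$missing_rate > 0 || config$het_error_rate > 0) {
    u <- matrix(runif(n * length(panel)), n)
    calls[u < config$het_error_rate] <- "H"
    calls[u >= config$het_error_rate &
          u < config$het_error_rate + config$missing_rate] <- "."
  }
  ids <- unlist(lapply(per_study, function(s) s$records$sample_id))
  dimnames(calls) <- list(ids, panel)

  records <- do.call(rbind, lapply(per_study, `[[`, "records"))
  truth <- do.call(rbind, lapply(per_study, `[[`, "truth"))
  truth$path <- vapply(classes[cls], function(cl)
    paste(paths[[cl]], collapse = ";"), character(1))
  rownames(records) <- rownames(truth) <- NULL
  list(genotypes = new_genotype_matrix(calls), records = records,
       truth = truth)
}

draw_study <- function(prof, config, classes, effect_lp) {
  want_case <- prof$n_cases
  want_ctrl <- prof$n_controls
  chunk <- max(2000L, 2L * (want_case + want_ctrl))
  pool <- NULL
  for (i in 1:60) {
    p_main <- setNames(numeric(length(classes)), classes)
    p_main[names(prof$leaf_freqs)] <- prof$leaf_freqs
    new <- data.frame(
      aj = runif(chunk) < prof$aj_fraction)
    if (prof$aj_fraction > 0) {
      p_aj <- setNames(numeric(length(classes)), classes)
      p_aj[names(prof$aj_leaf_freqs)] <- prof$aj_leaf_freqs
      new$class_idx <- ifelse(new$aj,
        sample.int(length(classes), chunk, replace = TRUE, prob = p_aj),
        sample.int(length(classes), chunk, replace = TRUE, prob = p_main))
      # ifelse() on two sampled vectors keeps per-row independence: both
      # draws use independent stream positions but identical length
    } else {
      new$class_idx <- sample.int(length(classes), chunk, replace = TRUE,
                                  prob = p_main)
    }
    new$age <- rtruncnorm1(chunk, prof$age_mean, prof$age_sd,
                           prof$age_range[1], prof$age_range[2])
    lp <- config$baseline_logit + prof$baseline_shift +
      effect_lp[new$class_idx] +
      config$age_log_or_per_decade * (new$age - 65) / 10
    new$lp <- lp
    new$is_case <- runif(chunk) < stats::plogis(lp)
    pool <- rbind(pool, new)
    if (sum(pool$is_case) >= want_case &&
        sum(!pool$is_case) >= want_ctrl) break
  }
  if (sum(pool$is_case) < want_case || sum(!pool$is_case) < want_ctrl)
    stop("could not reach target counts for study ", prof$study,
         "; adjust baseline_logit")
  take <- c(which(pool$is_case)[seq_len(want_case)],
            which(!pool$is_case)[seq_len(want_ctrl)])
  pool <- pool[take, , drop = FALSE]
  m <- nrow(pool)

  ev1 <- ifelse(pool$aj, -abs(rnorm(m, 0.020, 0.006)),
                abs(rnorm(m, 0.010, 0.004)))
  ev2 <- ifelse(pool$aj, abs(rnorm(m, 0.020, 0.006)),
                rnorm(m, 0, 0.008))
  pc1 <- rnorm(m, ifelse(pool$aj, 0.03, 0), 0.01)

  gleason <- rep(NA_integer_, m)
  stage <- rep(NA_integer_, m)
  ncase <- sum(pool$is_case)
  gleason[pool$is_case] <- sample(5:9, ncase, replace = TRUE,
                                  prob = c(0.08, 0.32, 0.38, 0.15, 0.07))
  stage[pool$is_case] <- sample(1:4, ncase, replace = TRUE,
                                prob = c(0.35, 0.35, 0.20, 0.10))
  gleason[pool$is_case][runif(ncase) < 0.03] <- NA_integer_
  stage[pool$is_case][runif(ncase) < 0.03] <- NA_integer_

  ids <- sprintf("%s_%05d", prof$study, seq_len(m))
  list(
    class_idx = pool$class_idx,
    records = data.frame(
      sample_id = ids, study = prof$study, is_case = pool$is_case,
      gleason = gleason, stage = stage,
      age_years = round(pool$age, 1),
      pc1 = pc1, ev1 = ev1, ev2 = ev2, stringsAsFactors = FALSE),
    truth = data.frame(
      sample_id = ids, study = prof$study, leaf = classes[pool$class_idx],
      path = NA_character_, aj_cluster = pool$aj,
      linear_predictor = pool$lp, is_case = pool$is_case,
      stringsAsFactors = FALSE))
}

#' Default Stage-I-like study profiles
#'
#' Four profiles emulating the haplogroup structure of a large
#' European-ancestry prostate cancer consortium: two continental-US studies
#' (R1b1a2-dominated, N1c rare), one French study (R1b1a2-dominated, least
#' I1) and one Finnish study with the characteristic N1c excess (0.556) and
#' I1 at 0.276 but few R1b carriers; E1b1b1c sits near 1% of pooled
#' controls and near 15.4% in the embedded AJ-like clusters of the US/French
#' studies, and is absent from the Finnish profile. Anchor frequencies are
#' published values; the remaining mass over other leaves, and the
#' case/control splits, are illustrative choices.
#'
#' @param scale Multiplier on the target case/control counts (default 1 =
#'   3,995 cases and 3,815 controls overall).
#' @return List of four [study_profile()] objects (PLCO, CPS-II, ATBC,
#'   CeRePP).
#' @export
stage1_profiles <- function(scale = 1) {
  # no mass on the F* and J* paragroups: the branch-imputation identities
  # (e.g. J1 = J minus J2) hold exactly only when they are empty, which is
  # the operating assumption of the tree-based analysis being emulated
  base <- list(
    "E1b1b" = 0.005, "E1b1b1a1" = 0.020, "E1b1b1b1" = 0.002,
    "G1" = 0.001, "G2a" = 0.025, "G2c" = 0.002,
    "I" = 0.010, "I2a1a" = 0.003, "I2b+I2c" = 0.040,
    "J1" = 0.012, "J2" = 0.033, "K" = 0.010, "T1" = 0.003,
    "N" = 0.002, "P" = 0.010, "Q" = 0.004, "R" = 0.005)
  finish <- function(v) {
    v <- unlist(v)
    v["R1a+R1*"] <- 1 - sum(v)
    check_freq_vector(v, "profile")
    v
  }
  plco <- finish(c(base, list("E1b1b1c" = 0.009, "I1" = 0.139,
                              "N1c" = 0.017, "R1b1a2" = 0.550,
                              "R1b1b+R1b*" = 0.040)))
  cpsii <- finish(c(base, list("E1b1b1c" = 0.009, "I1" = 0.112,
                               "N1c" = 0.008, "R1b1a2" = 0.560,
                               "R1b1b+R1b*" = 0.045)))
  cerepp <- finish(c(base, list("E1b1b1c" = 0.009, "I1" = 0.081,
                                "N1c" = 0.004, "R1b1a2" = 0.580,
                                "R1b1b+R1b*" = 0.070)))
  atbc <- finish(list(
    "E1b1b" = 0.002, "E1b1b1a1" = 0.002, "G1" = 0.001,
    "G2a" = 0.005, "I" = 0.005, "I1" = 0.276, "I2a1a" = 0.002,
    "I2b+I2c" = 0.015, "J1" = 0.002, "J2" = 0.005,
    "K" = 0.005, "T1" = 0.002, "N" = 0.020, "N1c" = 0.556, "P" = 0.005,
    "Q" = 0.002, "R" = 0.003, "R1b1a2" = 0.040, "R1b1b+R1b*" = 0.008))
  aj <- unlist(list(
    "E1b1b" = 0.05, "E1b1b1a1" = 0.06, "E1b1b1b1" = 0.01,
    "E1b1b1c" = 0.154, "G2a" = 0.04, "G2c" = 0.05, "I" = 0.02,
    "I1" = 0.04, "J1" = 0.16, "J2" = 0.16, "K" = 0.02,
    "Q" = 0.05, "R1b1a2" = 0.10, "T1" = 0.03))
  aj["R1a+R1*"] <- 1 - sum(aj)
  n <- function(x) as.integer(round(x * scale))
  list(
    study_profile("PLCO", n(1200), n(1150), plco,
                  aj_fraction = 0.04, aj_leaf_freqs = aj),
    study_profile("CPSII", n(1100), n(1050), cpsii,
                  aj_fraction = 0.04, aj_leaf_freqs = aj),
    study_profile("ATBC", n(950), n(900), atbc),
    study_profile("CeRePP", n(745), n(715), cerepp,
                  aj_fraction = 0.02, aj_leaf_freqs = aj))
}

#' Stage-I-like simulation configuration
#'
#' [sim_config()] prefilled with the packaged tree, [stage1_profiles()],
#' the 34-marker genotyping panel (the four imputation-only markers M203,
#' M522, M429 and M267 stay untyped) and mild genotyping noise.
#'
#' @param effect_map Named allelic ORs per branch (default: all null).
#' @param scale Passed to [stage1_profiles()].
#' @param missing_rate,het_error_rate Per-call noise (defaults 0.01 and
#'   0.001).
#' @param seed Seed stored in the configuration.
#' @return A `sim_config`.
#' @export
stage1_sim_config <- function(effect_map = numeric(0), scale = 1,
                              missing_rate = 0.01, het_error_rate = 0.001,
                              seed = 1L) {
  tree <- read_haplo_tree(yhap_example("y_tree.tsv"))
  sim_config(tree, stage1_profiles(scale), effect_map = effect_map,
             panel_exclude = c("M203", "M522", "M429", "M267"),
             missing_rate = missing_rate, het_error_rate = het_error_rate,
             seed = seed)
}

#' Bias, coverage and type-I error of the pipeline under simulation
#'
#' Runs the full pipeline (simulate, QC, branch assignment, covariate-
#' adjusted association) `replicates` times and summarizes, per requested
#' branch, the mean estimated allelic OR, the mean log-OR bias against the
#' configured truth, the coverage of the 95% Wald interval, and the
#' rejection rate at `alpha` (the type-I error for null branches, the
#' power for non-null ones).
#'
#' @param config A [sim_config()]; its seed initializes the stream, after
#'   which replicates consume consecutive RNG states.
#' @param replicates Number of simulated cohorts (>= 1).
#' @param branches Branch labels to track.
#' @param covariates A [covariate_spec()] used in every association fit.
#' @param subgroup Case subgroup tested (default `"overall"`).
#' @param alpha Rejection threshold (default 0.05).
#' @return Data.frame, one row per branch: `branch`, `true_or`,
#'   `replicates`, `n_estimated`, `mean_or`, `mean_log_or`, `bias_log_or`,
#'   `coverage`, `rejection_rate`, `n_fisher`, `n_untestable`.
#' @export
recovery_experiment <- function(config, replicates, branches,
                                covariates = covariate_spec(),
                                subgroup = "overall", alpha = 0.05) {
  stopifnot(inherits(config, "sim_config"), replicates >= 1)
  if (!is.null(config$seed)) set.seed(config$seed)
  true_or <- setNames(rep(1, length(branches)), branches)
  known <- intersect(branches, names(config$effect_map))
  true_or[known] <- config$effect_map[known]

  res <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    sim <- simulate_cohort(config, seed = NULL)
    geno <- apply_qc(sim$genotypes)
    carriers <- branch_status(geno, config$tree)
    res[[r]] <- do.call(rbind, lapply(branches, function(b)
      branch_association(carriers, sim$records, b, subgroup, covariates)))
  }
  all <- do.call(rbind, res)
  out <- lapply(branches, function(b) {
    d <- all[all$branch == b, , drop = FALSE]
    est <- d$method != "untestable" & is.finite(d$or_estimate) &
           d$or_estimate > 0
    lo <- log(true_or[b])
    data.frame(
      branch = b, true_or = unname(true_or[b]), replicates = replicates,
      n_estimated = sum(est),
      mean_or = mean(d$or_estimate[est]),
      mean_log_or = mean(log(d$or_estimate[est])),
      bias_log_or = mean(log(d$or_estimate[est])) - lo,
      coverage = mean(d$ci_low[est] <= true_or[b] &
                      d$ci_high[est] >= true_or[b]),
      rejection_rate = mean(d$p_value <= alpha, na.rm = TRUE),
      n_fisher = sum(d$method == "fisher"),
      n_untestable = sum(d$method == "untestable"),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
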