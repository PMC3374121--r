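# Per-branch case-control association: covariate-adjusted score test,
# allelic OR with Wald CI, Fisher exact fallback.

#' Covariate specification for the association models
#'
#' Age enters as a factor over 10-year bins anchored at decade boundaries,
#' with everything below the first break its own bin ("age < 50" by
#' default); study and the first principal component of population
#' stratification are optional additive adjustments. Covariate factor
#' categories that contain no cases (or no controls) among the samples
#' entering a model carry no information about the carrier effect and are
#' dropped, together with their samples, when `drop_empty_strata` is set.
#'
#' @param age_breaks Increasing break points for the age bins; `-Inf`/`Inf`
#'   ends are added automatically.
#' @param include_age,include_study,include_pc1 Include the corresponding
#'   adjustment term.
#' @param drop_empty_strata Drop covariate factor categories with no cases
#'   or no controls before fitting.
#' @return A `covariate_spec` list.
#' @export
covariate_spec <- function(age_breaks = c(50, 60, 70, 80),
                           include_age = TRUE,
                           include_study = TRUE,
                           include_pc1 = TRUE,
                           drop_empty_strata = TRUE) {
  if (is.unsorted(age_breaks, strictly = TRUE))
    stop("age_breaks must be strictly increasing")
  structure(list(age_breaks = age_breaks, include_age = include_age,
                 include_study = include_study, include_pc1 = include_pc1,
                 drop_empty_strata = drop_empty_strata),
            class = "covariate_spec")
}

#' No-adjustment covariate specification
#'
#' Intercept-only models: the score test then reduces to the Pearson
#' chi-square of the 2x2 carrier-by-outcome table.
#'
#' @return A `covariate_spec` with every adjustment switched off.
#' @export
no_covariates <- function() {
  covariate_spec(include_age = FALSE, include_study = FALSE,
                 include_pc1 = FALSE, drop_empty_strata = FALSE)
}

age_bin <- function(age, breaks) {
  cut(age, breaks = c(-Inf, breaks, Inf), right = FALSE)
}

# Assemble y, carrier x and covariate data for one model. Drops samples
# with missing carrier status or missing required covariates, then applies
# the empty-stratum rule.
assemble_model_data <- function(carriers, records, branch, keep_ids,
                                y, covariates) {
  idx <- match(keep_ids, carriers$sample_ids)
  x <- carriers$status[idx, branch]
  rec <- records[match(keep_ids, records$sample_id), , drop = FALSE]
  d <- data.frame(y = y, x = x, stringsAsFactors = FALSE)
  if (covariates$include_age) d$age_bin <- age_bin(rec$age_years,
                                                   covariates$age_breaks)
  if (covariates$include_study) d$study <- factor(rec$study)
  if (covariates$include_pc1) d$pc1 <- rec$pc1
  ok <- stats::complete.cases(d)
  d <- d[ok, , drop = FALSE]

  dropped <- character(0)
  if (covariates$drop_empty_strata) {
    repeat {
      removed <- FALSE
      for (v in intersect(c("age_bin", "study"), names(d))) {
        d[[v]] <- droplevels(d[[v]])
        tab <- table(d[[v]], d$y)
        bad <- rownames(tab)[tab[, 1] == 0L | tab[, 2] == 0L]
        if (length(bad)) {
          dropped <- c(dropped, paste0(v, "=", bad))
          d <- d[!(d[[v]] %in% bad), , drop = FALSE]
          removed <- TRUE
        }
      }
      if (!removed) break
    }
  }
  for (v in intersect(c("age_bin", "study"), names(d)))
    d[[v]] <- droplevels(d[[v]])
  attr(d, "dropped_strata") <- dropped
  d
}

covariate_formula_rhs <- function(d) {
  terms <- intersect(c("age_bin", "study", "pc1"), names(d))
  # a factor reduced to one level (e.g. after stratum dropping) is constant
  terms <- terms[vapply(terms, function(v)
    !is.factor(d[[v]]) || nlevels(d[[v]]) > 1L, logical(1))]
  if (length(terms) == 0L) "1" else paste(terms, collapse = " + ")
}

# Rao score test of adding x to the null logistic model y ~ X0.
# Returns the 1-df chi-square statistic.
score_statistic <- function(y, x, X0) {
  fit0 <- glm.fit(X0, y, family = binomial(),
                  control = list(epsilon = 1e-12, maxit = 100))
  if (!fit0$converged)
    stop("IRLS for the null logistic model did not converge after ",
         fit0$iter, " iterations")
  p <- fit0$fitted.values
  w <- p * (1 - p)
  U <- sum(x * (y - p))
  a <- crossprod(X0, w * x)                    # k x 1
  V00 <- crossprod(X0, X0 * w)
  V <- sum(w * x^2) - drop(crossprod(a, solve(V00, a)))
  if (V <= .Machine$double.eps)
    return(list(stat = NA_real_, p_value = NA_real_))
  stat <- drop(U^2 / V)
  list(stat = stat, p_value = pchisq(stat, df = 1L, lower.tail = FALSE))
}

#' Case-control association for one branch bipartition
#'
#' Tests whether derived-allele carriers of one haplogroup branch differ in
#' disease odds from non-carriers, within a case subgroup. The p-value is
#' the 1-df Rao score test of adding the binary carrier indicator to a null
#' logistic model holding only the covariates (fitted by iteratively
#' reweighted least squares); the allelic odds ratio and 95% Wald
#' confidence interval come from the fitted alternative model. On the
#' haploid Y each man carries a single allele, so the allelic OR equals the
#' carrier OR and "MAF" is a frequency over men. When any cell of the
#' carrier-by-outcome 2x2 table is empty (including perfect separation),
#' the method falls back to the Fisher exact test with conditional-MLE OR
#' and exact CI; a branch with no carriers or no non-carriers is reported
#' untestable.
#'
#' @param carriers A `branch_carrier_matrix` from [branch_status()].
#' @param records Sample-record data.frame.
#' @param branch Branch label to test.
#' @param subgroup One of `"overall"` (all cases), `"nonaggressive"` or
#'   `"aggressive"` (cases restricted by [classify_aggressiveness()];
#'   controls always included).
#' @param covariates A [covariate_spec()].
#' @return An `assoc_result` (one-row data.frame): `branch`, `subgroup`,
#'   `n_controls`, `n_cases` (samples with called status entering the
#'   model), `maf_controls`, `maf_cases`, `score_stat`, `p_value`,
#'   `or_estimate`, `ci_low`, `ci_high`, `method` (`"score"`, `"fisher"` or
#'   `"untestable"`) and `n_dropped_strata`.
#' @export
branch_association <- function(carriers, records, branch,
                               subgroup = c("overall", "nonaggressive",
                                            "aggressive"),
                               covariates = covariate_spec()) {
  subgroup <- match.arg(subgroup)
  stopifnot(inherits(carriers, "branch_carrier_matrix"))
  if (!branch %in% colnames(carriers$status))
    stop("unknown branch: ", branch)
  rec <- records[match(carriers$sample_ids, records$sample_id), ,
                 drop = FALSE]
  grp <- classify_aggressiveness(rec)
  use <- switch(subgroup,
    overall = rep(TRUE, nrow(rec)),
    nonaggressive = grp %in% c("control", "nonaggressive"),
    aggressive = grp %in% c("control", "aggressive"))
  ids <- carriers$sample_ids[use]
  y <- as.integer(rec$is_case[use])

  d <- assemble_model_data(carriers, records, branch, ids, y, covariates)
  result_shell <- function(method, d) {
    data.frame(branch = branch, subgroup = subgroup,
               n_controls = sum(d$y == 0L), n_cases = sum(d$y == 1L),
               maf_controls = if (sum(d$y == 0L)) mean(d$x[d$y == 0L])
                              else NA_real_,
               maf_cases = if (sum(d$y == 1L)) mean(d$x[d$y == 1L])
                           else NA_real_,
               score_stat = NA_real_, p_value = NA_real_,
               or_estimate = NA_real_, ci_low = NA_real_,
               ci_high = NA_real_, method = method,
               n_dropped_strata = length(attr(d, "dropped_strata")),
               stringsAsFactors = FALSE)
  }
  if (sum(d$y == 1L) == 0L || sum(d$y == 0L) == 0L)
    return(structure(result_shell("untestable", d),
                     class = c("assoc_result", "data.frame")))
  if (all(d$x == 1L) || all(d$x == 0L))
    return(structure(result_shell("untestable", d),
                     class = c("assoc_result", "data.frame")))

  out <- result_shell("score", d)
  tab <- carrier_table(d)
  if (any(tab == 0L)) {
    fe <- fisher_exact_or(tab)
    out$method <- "fisher"
    out$p_value <- fe$p_value
    out$or_estimate <- fe$or_estimate
    out$ci_low <- fe$ci_low
    out$ci_high <- fe$ci_high
  } else {
    rhs <- covariate_formula_rhs(d)
    X0 <- model.matrix(stats::as.formula(paste("~", rhs)), data = d)
    sc <- score_statistic(d$y, d$x, X0)
    out$score_stat <- sc$stat
    out$p_value <- sc$p_value
    fit1 <- glm(stats::as.formula(paste("y ~ x +", rhs)),
                family = binomial(), data = d)
    beta <- stats::coef(fit1)["x"]
    se <- sqrt(diag(stats::vcov(fit1))["x"])
    if (!is.finite(beta) || abs(beta) > 10) {   # separation guard
      fe <- fisher_exact_or(tab)
      out$method <- "fisher"
      out$p_value <- fe$p_value
      out$score_stat <- NA_real_
      out$or_estimate <- fe$or_estimate
      out$ci_low <- fe$ci_low
      out$ci_high <- fe$ci_high
    } else {
      z <- qnorm(0.975)
      out$or_estimate <- exp(unname(beta))
      out$ci_low <- exp(unname(beta - z * se))
      out$ci_high <- exp(unname(beta + z * se))
    }
  }
  structure(out, class = c("assoc_result", "data.frame"))
}

# 2x2 carrier x outcome table: rows carrier/non-carrier, cols case/control
carrier_table <- function(d) {
  matrix(c(sum(d$x == 1L & d$y == 1L), sum(d$x == 1L & d$y == 0L),
           sum(d$x == 0L & d$y == 1L), sum(d$x == 0L & d$y == 0L)),
         nrow = 2L, byrow = TRUE,
         dimnames = list(c("carrier", "noncarrier"),
                         c("case", "control")))
}

#' Association results across branches and subgroups
#'
#' Convenience driver calling [branch_association()] over a grid of
#' branches and case subgroups, mirroring the layout of a published
#' association table. When a tree is supplied, locus and allele annotations
#' of each branch's first defining marker are joined on.
#'
#' @inheritParams branch_association
#' @param branches Branch labels (default: every branch in `carriers`).
#' @param subgroups Subset of `c("overall", "nonaggressive", "aggressive")`.
#' @param tree Optional `haplo_tree` for marker annotation columns.
#' @return Data.frame of stacked `assoc_result` rows (plus `locus`,
#'   `alleles` when `tree` is given).
#' @export
run_association <- function(carriers, records,
                            branches = NULL,
                            subgroups = c("overall", "nonaggressive",
                                          "aggressive"),
                            covariates = covariate_spec(),
                            tree = NULL) {
  if (is.null(branches)) branches <- colnames(carriers$status)
  rows <- list()
  for (b in branches) for (s in subgroups)
    rows[[paste(b, s)]] <- branch_association(carriers, records, b, s,
                                              covariates)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(tree)) {
    first_marker <- vapply(out$branch, function(b) {
      mk <- tree$nodes[[b]]$markers
      if (length(mk)) mk[1] else NA_character_
    }, character(1))
    mi <- match(first_marker, tree$markers$name)
    out$locus <- first_marker
    out$alleles <- ifelse(is.na(mi), NA_character_,
                          paste0(tree$markers$ancestral[mi], "|",
                                 tree$markers$derived[mi]))
  }
  out
}

#' Case-only test of carrier effect difference between case groups
#'
#' Among classified cases only, tests whether carrier frequency differs
#' between aggressive and non-aggressive disease: a logistic model of
#' aggressive (vs non-aggressive) outcome with the same covariate
#' adjustment, scored for the carrier indicator. A near-null p-value here
#' means the branch effect, if any, does not distinguish the two case
#' groups.
#'
#' @inheritParams branch_association
#' @return List with `p_value`, `score_stat`, `n_nonaggressive`,
#'   `n_aggressive`, `method`.
#' @export
case_group_difference <- function(carriers, records, branch,
                                  covariates = covariate_spec()) {
  stopifnot(inherits(carriers, "branch_carrier_matrix"))
  rec <- records[match(carriers$sample_ids, records$sample_id), ,
                 drop = FALSE]
  grp <- classify_aggressiveness(rec)
  use <- grp %in% c("nonaggressive", "aggressive")
  if (!any(grp == "nonaggressive") || !any(grp == "aggressive"))
    stop("both case subgroups must be non-empty")
  ids <- carriers$sample_ids[use]
  y <- as.integer(grp[use] == "aggressive")
  d <- assemble_model_data(carriers, records, branch, ids, y, covariates)
  n0 <- sum(d$y == 0L); n1 <- sum(d$y == 1L)
  if (n0 == 0L || n1 == 0L || all(d$x == d$x[1]))
    return(list(p_value = NA_real_, score_stat = NA_real_,
                n_nonaggressive = n0, n_aggressive = n1,
                method = "untestable"))
  tab <- carrier_table(d)
  if (any(tab == 0L)) {
    fe <- fisher_exact_or(tab)
    return(list(p_value = fe$p_value, score_stat = NA_real_,
                n_nonaggressive = n0, n_aggressive = n1,
                method = "fisher"))
  }
  X0 <- model.matrix(stats::as.formula(paste("~", covariate_formula_rhs(d))),
                     data = d)
  sc <- score_statistic(d$y, d$x, X0)
  list(p_value = sc$p_value, score_stat = sc$stat,
       n_nonaggressive = n0, n_aggressive = n1, method = "score")
}

#' Fisher exact test with conditional-MLE odds ratio for a 2x2 table
#'
#' Exact inference for sparse carrier-by-outcome tables: the two-sided
#' p-value sums the hypergeometric probabilities of all tables with the
#' observed margins whose probability does not exceed that of the observed
#' table; the odds ratio is the conditional maximum-likelihood estimate
#' with its exact confidence interval. A zero carrier-case cell yields an
#' OR estimate of 0 with a finite upper confidence bound.
#'
#' @param table 2x2 matrix of non-negative integer counts
#'   (rows carrier/non-carrier, columns case/control).
#' @param conf_level Confidence level for the exact CI (default 0.95).
#' @return List: `p_value`, `or_estimate`, `ci_low`, `ci_high`,
#'   `method = "fisher"`.
#' @export
fisher_exact_or <- function(table, conf_level = 0.95) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("table must be 2x2")
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers")
  if (any(rowSums(table) == 0L) || any(colSums(table) == 0L))
    stop("untestable: empty table margin")
  ft <- fisher.test(table, conf.level = conf_level)
  list(p_value = ft$p.value,
       or_estimate = unname(ft$estimate),
       ci_low = ft$conf.int[1],
       ci_high = ft$conf.int[2],
       method = "fisher")
}
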