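test_that("J1 carrier status is imputed from a derived J and ancestral J2", {
  calls <- matrix(c("D", "A",     # J derived, J2 ancestral -> J1 carrier
                    "D", "D",     # inside J2 -> J1 non-carrier
                    "A", "A"),    # outside J -> J1 non-carrier
                  3, 2, byrow = TRUE,
                  dimnames = list(paste0("s", 1:3), c("M304", "M172")))
  co <- make_cohort(calls)
  carr <- branch_status(apply_qc(co$genotypes), j_tree())
  expect_equal(unname(carr$provenance["J1"]), "imputed")
  expect_equal(unname(carr$status[, "J1"]), c(1L, 0L, 0L))
  # missing input propagates to missing imputation
  calls2 <- calls; calls2[1, "M172"] <- "."
  co2 <- make_cohort(calls2)
  # relax the completion threshold: with a 2-marker panel one missing call
  # is half the panel, and sample QC is not what is under test here
  carr2 <- branch_status(apply_qc(co2$genotypes,
                                  completion_threshold = 0.4), j_tree())
  expect_true(is.na(carr2$status[1, "J1"]))
})

test_that("all-ancestral calls give non-carrier at every typed branch", {
  tr <- packaged_tree()
  calls <- matrix("A", 2, 34,
                  dimnames = list(c("s1", "s2"), panel_34(tr)))
  calls[2, "M96"] <- "D"          # keeps at least one marker polymorphic
  co <- make_cohort(calls)
  carr <- branch_status(apply_qc(co$genotypes), tr)
  expect_true(all(carr$status["s1", carr$typed_branches] == 0L))
})

test_that("a derived call under an ancestral ancestor is blanked as a conflict", {
  calls <- matrix(c("A", "D"), 1, 2,   # J ancestral but J2 derived
                  dimnames = list("s1", c("M304", "M172")))
  calls <- rbind(calls, s2 = c("D", "D"), s3 = c("D", "A"))
  co <- make_cohort(calls)
  carr <- branch_status(apply_qc(co$genotypes), j_tree())
  expect_true(is.na(carr$status["s1", "J"]))
  expect_true(is.na(carr$status["s1", "J2"]))
  expect_equal(carr$n_conflicts, 2L)
  expect_equal(unname(carr$status["s2", c("J", "J2")]), c(1L, 1L))
})

test_that("markers absent from the tree are an error", {
  calls <- matrix("A", 1, 1, dimnames = list("s1", "MZZ"))
  co <- make_cohort(calls)
  expect_error(branch_status(apply_qc(co$genotypes), j_tree()), "MZZ")
})

test_that("noiseless simulated carriers match generating paths at every branch", {
  cfg <- stage1_sim_config(seed = 21L, scale = 0.07,
                           missing_rate = 0, het_error_rate = 0)
  sim <- simulate_cohort(cfg)
  carr <- branch_status(apply_qc(sim$genotypes), cfg$tree)
  expect_equal(carr$n_conflicts, 0L)
  truth_paths <- strsplit(sim$truth$path, ";", fixed = TRUE)
  names(truth_paths) <- sim$truth$sample_id
  for (b in colnames(carr$status)) {
    truth_carrier <- vapply(truth_paths[carr$sample_ids],
                            function(p) b %in% p, logical(1))
    expect_equal(unname(carr$status[, b]), as.integer(truth_carrier),
                 info = b)
  }
  # carrier branches per man form a connected root-to-node chain
  hap <- assigned_haplogroup(carr)
  expect_false(anyNA(hap))
  for (s in sample(carr$sample_ids, 50)) {
    carried <- colnames(carr$status)[carr$status[s, ] == 1L]
    expect_setequal(carried,
                    intersect(tree_path(cfg$tree, hap[s]),
                              colnames(carr$status)))
  }
})

test_that("ancestor closure holds under missingness", {
  cfg <- stage1_sim_config(seed = 22L, scale = 0.05, missing_rate = 0.05)
  sim <- simulate_cohort(cfg)
  carr <- branch_status(apply_qc(sim$genotypes), cfg$tree)
  st <- carr$status
  for (b in colnames(st)) {
    for (a in intersect(yhapassoc:::tree_ancestors(cfg$tree, b),
                        colnames(st))) {
      bad <- !is.na(st[, b]) & st[, b] == 1L &
             !is.na(st[, a]) & st[, a] == 0L
      expect_equal(sum(bad), 0L, info = paste(b, "under", a))
    }
  }
})

test_that("frequency tables stratify correctly and ignore sample order", {
  cfg <- stage1_sim_config(seed = 23L, scale = 0.1)
  sim <- simulate_cohort(cfg)
  carr <- branch_status(apply_qc(sim$genotypes), cfg$tree)
  fr <- haplogroup_frequencies(carr, sim$records, "study",
                               branches = c("N1c", "R1b1a2"))
  expect_setequal(unique(fr$study), c("PLCO", "CPSII", "ATBC", "CeRePP"))
  expect_true(all(fr$derived_freq >= 0 & fr$derived_freq <= 1))
  expect_true(all(fr$n_called <= table(sim$records$study)[fr$study]))

  shuf <- sim$records[sample(nrow(sim$records)), ]
  fr2 <- haplogroup_frequencies(carr, shuf, "study",
                                branches = c("N1c", "R1b1a2"))
  expect_equal(fr, fr2)

  expect_error(haplogroup_frequencies(carr, sim$records, "nope"),
               "unknown stratification key")
})

test_that("a stratum of one called carrier has frequency 1", {
  calls <- matrix(c("D", "A"), 2, 1,
                  dimnames = list(c("s1", "s2"), "M1"))
  tr <- haplo_tree_from_text(
    "node\tparent\tmarkers\nY\tROOT\t\nX\tY\tM1:A>G\n")
  co <- make_cohort(calls, study = c("one", "two"))
  carr <- branch_status(apply_qc(co$genotypes), tr)
  fr <- haplogroup_frequencies(carr, co$records, "study", branches = "X")
  expect_equal(fr$derived_freq[fr$study == "one"], 1)
  expect_equal(fr$n_called[fr$study == "one"], 1L)
})

test_that("leaf-class frequencies partition to unity on error-free data", {
  cfg <- stage1_sim_config(seed = 24L, scale = 0.07,
                           missing_rate = 0, het_error_rate = 0)
  sim <- simulate_cohort(cfg)
  carr <- branch_status(apply_qc(sim$genotypes), cfg$tree)
  hap <- assigned_haplogroup(carr)
  tab <- table(hap) / length(hap)
  expect_equal(sum(tab), 1)
  # display pooling conserves total frequency within each stratum
  fr <- haplogroup_frequencies(carr, sim$records, "study")
  disp <- display_frequencies(fr, min_freq = 0.05)
  for (s in unique(fr$study)) {
    expect_equal(sum(disp$derived_freq[disp$study == s]),
                 sum(fr$derived_freq[fr$study == s]))
  }
})

test_that("aggressiveness classification follows grade and stage rules", {
  rec <- data.frame(
    sample_id = paste0("s", 1:8),
    is_case = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE),
    gleason = c(6L, 7L, NA, NA, 6L, 9L, NA, NA),
    stage   = c(2L, 1L, 3L, 2L, NA, NA, NA, NA))
  got <- classify_aggressiveness(rec)
  expect_equal(as.character(got),
               c("nonaggressive",   # Gleason 6, stage II
                 "aggressive",      # Gleason 7, stage I
                 "aggressive",      # stage III alone decides
                 "unclassified",    # stage II alone cannot rule out G>=7
                 "unclassified",    # Gleason 6 alone cannot rule out stage
                 "aggressive",      # Gleason 9 alone decides
                 "control",
                 "unclassified"))
})

test_that("substructure cluster flag follows the EV sign rule", {
  rec <- data.frame(ev1 = c(-0.01, 0.01, -0.01, NA),
                    ev2 = c(0.02, 0.02, -0.02, 0.02))
  expect_equal(classify_substructure(rec), c(TRUE, FALSE, FALSE, NA))
  # thresholds are configurable
  expect_equal(classify_substructure(rec, ev1_max = 0.02)[2], TRUE)
})
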