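# Shared fixtures: tiny trees, in-memory cohorts, random tree generator.

tiny_tree_text <- function() {
  paste(
    "node\tparent\tmarkers",
    "Y\tROOT\t",
    "E\tY\tM96:C>G",
    "E1b1b\tE\tM215:T>C",
    sep = "\n")
}

# J-clade tree used throughout the imputation tests
j_tree <- function() {
  haplo_tree_from_text(paste(
    "node\tparent\tmarkers",
    "Y\tROOT\t",
    "J\tY\tM304:A>C",
    "J1\tJ\tM267:T>G",
    "J2\tJ\tM172:T>G",
    sep = "\n"))
}

packaged_tree <- function() read_haplo_tree(yhap_example("y_tree.tsv"))

panel_34 <- function(tree = packaged_tree()) {
  setdiff(tree$markers$name, c("M203", "M522", "M429", "M267"))
}

# Build a cohort from a wide call matrix + minimal phenotypes, going
# through the public file interface so the IO path is exercised too.
make_cohort <- function(calls, is_case = NULL, study = "S", age = 60,
                        pc1 = 0, ev1 = 0.01, ev2 = 0,
                        gleason = NULL, stage = NULL) {
  n <- nrow(calls)
  if (is.null(is_case)) is_case <- rep(FALSE, n)
  if (is.null(gleason)) gleason <- ifelse(is_case, 7L, NA_integer_)
  if (is.null(stage)) stage <- ifelse(is_case, 2L, NA_integer_)
  gf <- tempfile(fileext = ".tsv")
  pf <- tempfile(fileext = ".tsv")
  gdf <- data.frame(sample_id = rownames(calls), calls,
                    check.names = FALSE)
  write.table(gdf, gf, sep = "\t", quote = FALSE, row.names = FALSE)
  pdf <- data.frame(sample_id = rownames(calls),
                    study = rep_len(study, n),
                    is_case = as.integer(is_case),
                    gleason = gleason, stage = stage,
                    age_years = rep_len(age, n),
                    pc1 = rep_len(pc1, n),
                    ev1 = rep_len(ev1, n), ev2 = rep_len(ev2, n))
  write.table(pdf, pf, sep = "\t", quote = FALSE, row.names = FALSE,
              na = ".")
  read_cohort(gf, pf)
}

# cohort realizing a 2x2 carrier x outcome table on a single-marker tree
table_cohort <- function(a_case_carrier, b_ctrl_carrier,
                         c_case_non, d_ctrl_non) {
  n <- a_case_carrier + b_ctrl_carrier + c_case_non + d_ctrl_non
  calls <- matrix(rep(c("D", "D", "A", "A"),
                      c(a_case_carrier, b_ctrl_carrier, c_case_non,
                        d_ctrl_non)),
                  ncol = 1,
                  dimnames = list(sprintf("s%05d", seq_len(n)), "M1"))
  is_case <- rep(c(TRUE, FALSE, TRUE, FALSE),
                 c(a_case_carrier, b_ctrl_carrier, c_case_non, d_ctrl_non))
  tr <- haplo_tree_from_text(
    "node\tparent\tmarkers\nY\tROOT\t\nX\tY\tM1:A>G\n")
  co <- make_cohort(calls, is_case = is_case)
  carr <- branch_status(apply_qc(co$genotypes), tr)
  list(carriers = carr, records = co$records)
}

# random rooted tree with a marker on every non-root node
random_tree <- function(n_nodes, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  labs <- c("Y", sprintf("N%02d", seq_len(n_nodes - 1L)))
  parent <- c("ROOT", labs[vapply(2:n_nodes, function(i)
    sample.int(i - 1L, 1L), integer(1))])
  lines <- c("node\tparent\tmarkers",
             paste0(labs, "\t", parent, "\t",
                    ifelse(parent == "ROOT", "",
                           paste0("MK", seq_len(n_nodes), ":A>G"))))
  haplo_tree_from_text(paste(lines, collapse = "\n"))
}

# single-pass imputability by direct enumeration (the spec's brute force)
brute_imputable <- function(tree, typed) {
  cand <- setdiff(
    names(tree$nodes)[vapply(tree$nodes, function(n)
      length(n$markers) > 0L, logical(1))],
    c(typed, tree$root))
  ok <- vapply(cand, function(b) {
    p <- tree$nodes[[b]]$parent
    sibs <- setdiff(tree$nodes[[p]]$children, b)
    (is.na(p) || p == tree$root || p %in% typed) && all(sibs %in% typed)
  }, logical(1))
  sort(cand[ok])
}
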