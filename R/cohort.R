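# Genotype/phenotype IO and Y-specific quality control.

VALID_CALLS <- c("A", "D", "H", ".")

new_genotype_matrix <- function(calls, qc_applied = FALSE,
                                sample_qc = NULL, marker_qc = NULL) {
  structure(list(calls = calls,
                 sample_ids = rownames(calls),
                 marker_names = colnames(calls),
                 qc_applied = qc_applied,
                 sample_qc = sample_qc,
                 marker_qc = marker_qc),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$calls), "samples x",
      ncol(x$calls), "markers")
  if (isTRUE(x$qc_applied)) {
    cat(" (QC applied:", sum(x$sample_qc$excluded), "samples excluded,",
        sum(x$marker_qc$excluded), "markers excluded)")
  }
  cat("\n")
  invisible(x)
}

#' Read an aligned genotype + phenotype cohort
#'
#' The genotype table is TSV, canonical wide form: a `sample_id` column plus
#' one column per marker, with call tokens `A` (ancestral), `D` (derived),
#' `H` (heterozygous — an impossible diploid-style call on the hemizygous Y,
#' kept as a genotyping-error signal) and `.` (missing; empty cells and `NA`
#' are also read as missing). A long form with columns
#' `sample_id`, `marker`, `call` is accepted and pivoted. The phenotype
#' table is TSV with header
#' `sample_id study is_case gleason stage age_years pc1 ev1 ev2`;
#' `is_case` is 0/1 (or TRUE/FALSE), `stage` may be arabic 1-4 or roman
#' I-IV, and gleason/stage/pc1/ev1/ev2 may be missing (`.` or `NA`).
#' Controls must have missing gleason and stage.
#'
#' Every genotyped sample must appear in the phenotype table (orphans are an
#' error); phenotype-only samples are dropped with a message. Records are
#' returned in genotype-row order.
#'
#' @param genotype_file,phenotype_file Paths (or connections) to the tables.
#' @return A list with `genotypes` (a `genotype_matrix`) and `records` (a
#'   data.frame of sample records).
#' @export
read_cohort <- function(genotype_file, phenotype_file) {
  geno <- read.delim(genotype_file, header = TRUE, sep = "\t",
                     colClasses = "character", check.names = FALSE)
  if (!"sample_id" %in% names(geno))
    stop("genotype table needs a sample_id column")
  if (all(c("marker", "call") %in% names(geno)) && ncol(geno) == 3L) {
    # long form -> wide
    wide <- tapply(geno$call, list(geno$sample_id, geno$marker),
                   function(v) v[1])
    dup <- duplicated(geno[c("sample_id", "marker")])
    if (any(dup)) stop("duplicate sample/marker pair(s) in long table")
    calls <- unclass(wide)
  } else {
    if (anyDuplicated(geno$sample_id))
      stop("duplicate sample id(s): ",
           paste(unique(geno$sample_id[duplicated(geno$sample_id)]),
                 collapse = ", "))
    calls <- as.matrix(geno[setdiff(names(geno), "sample_id")])
    rownames(calls) <- geno$sample_id
  }
  calls[is.na(calls) | calls == "" | calls == "NA"] <- "."
  bad <- matrix(!(calls %in% VALID_CALLS), nrow(calls))
  if (any(bad)) {
    i <- which(bad, arr.ind = TRUE)[1, ]
    stop("unknown call token '", calls[bad][1], "' for sample ",
         rownames(calls)[i[1]], ", marker ", colnames(calls)[i[2]])
  }

  rec <- read_phenotypes(phenotype_file)
  orphans <- setdiff(rownames(calls), rec$sample_id)
  if (length(orphans))
    stop("genotyped sample(s) absent from phenotype table: ",
         paste(orphans, collapse = ", "))
  extra <- setdiff(rec$sample_id, rownames(calls))
  if (length(extra))
    message(length(extra), " phenotype-only sample(s) dropped")
  rec <- rec[match(rownames(calls), rec$sample_id), , drop = FALSE]
  rownames(rec) <- NULL
  list(genotypes = new_genotype_matrix(calls), records = rec)
}

read_phenotypes <- function(file) {
  rec <- read.delim(file, header = TRUE, sep = "\t",
                    colClasses = "character", na.strings = c("NA", "."))
  need <- c("sample_id", "study", "is_case", "gleason", "stage",
            "age_years", "pc1", "ev1", "ev2")
  miss <- setdiff(need, names(rec))
  if (length(miss))
    stop("phenotype table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(rec$sample_id))
    stop("duplicate sample id(s) in phenotype table: ",
         paste(unique(rec$sample_id[duplicated(rec$sample_id)]),
               collapse = ", "))
  roman <- c(I = 1L, II = 2L, III = 3L, IV = 4L)
  stage <- rec$stage
  is_rom <- !is.na(stage) & stage %in% names(roman)
  stage[is_rom] <- roman[stage[is_rom]]
  out <- data.frame(
    sample_id = rec$sample_id,
    study = rec$study,
    is_case = as.logical(as.integer(rec$is_case)),
    gleason = as.integer(rec$gleason),
    stage = as.integer(stage),
    age_years = as.numeric(rec$age_years),
    pc1 = as.numeric(rec$pc1),
    ev1 = as.numeric(rec$ev1),
    ev2 = as.numeric(rec$ev2),
    stringsAsFactors = FALSE)
  if (any(is.na(out$is_case))) stop("is_case must be 0/1 for every sample")
  if (any(!is.na(out$age_years) & out$age_years <= 0))
    stop("age_years must be positive")
  ctrl_staged <- !out$is_case & (!is.na(out$gleason) | !is.na(out$stage))
  if (any(ctrl_staged))
    stop("control sample(s) carry gleason/stage: ",
         paste(out$sample_id[ctrl_staged], collapse = ", "))
  out
}

#' Write a cohort back to genotype and phenotype TSV files
#'
#' Inverse of [read_cohort()] (wide genotype form); round-trips losslessly.
#'
#' @param genotypes A `genotype_matrix`.
#' @param records Sample-record data.frame as returned by [read_cohort()].
#' @param genotype_file,phenotype_file Output paths.
#' @return Invisibly, the two paths.
#' @export
write_cohort <- function(genotypes, records, genotype_file, phenotype_file) {
  gdf <- data.frame(sample_id = rownames(genotypes$calls),
                    genotypes$calls, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(gdf, genotype_file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  rec <- records
  rec$is_case <- as.integer(rec$is_case)
  write.table(rec, phenotype_file, sep = "\t", quote = FALSE,
              row.names = FALSE, na = ".")
  invisible(c(genotype_file, phenotype_file))
}

#' Apply sample- and marker-level quality control
#'
#' Sample exclusions come first: a sample is excluded when its call
#' completion rate (called markers over all attempted markers, heterozygous
#' calls counting as called attempts) is strictly below
#' `completion_threshold`, or when it has `het_limit` or more heterozygous
#' calls — on the hemizygous Y a heterozygous call can only be a genotyping
#' error, and repeated errors indicate an unreliable sample. Markers that
#' are monomorphic among the retained samples are then flagged and excluded
#' from the analysis set (their calls are kept: an all-ancestral marker
#' still proves that nobody carries its branch, which matters for
#' imputation). Finally, surviving isolated heterozygous calls in retained
#' samples are set to missing rather than coerced to an allele.
#'
#' Applying QC twice is a no-op: an already-QC'd object is returned
#' unchanged.
#'
#' @param genotypes A `genotype_matrix`.
#' @param completion_threshold Minimum completion rate (default 0.80;
#'   exclusion is strict: exactly 80% is retained).
#' @param het_limit Heterozygous-call count at which a sample is excluded
#'   (default 2).
#' @return The `genotype_matrix` with `qc_applied = TRUE`, per-sample QC
#'   table `sample_qc` (`sample_id`, `completion`, `n_het`, `excluded`,
#'   `reason`) and per-marker table `marker_qc` (`marker`, `monomorphic`,
#'   `excluded`).
#' @export
apply_qc <- function(genotypes, completion_threshold = 0.80, het_limit = 2L) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (isTRUE(genotypes$qc_applied)) return(genotypes)
  calls <- genotypes$calls
  completion <- rowMeans(calls != ".")
  n_het <- rowSums(calls == "H")
  low_comp <- completion < completion_threshold
  many_het <- n_het >= het_limit
  excluded <- low_comp | many_het
  reason <- rep(NA_character_, nrow(calls))
  reason[many_het] <- "heterozygosity"
  reason[low_comp] <- ifelse(many_het[low_comp],
                             "completion;heterozygosity", "completion")
  sample_qc <- data.frame(sample_id = rownames(calls),
                          completion = completion, n_het = n_het,
                          excluded = excluded, reason = reason,
                          stringsAsFactors = FALSE)

  kept <- calls[!excluded, , drop = FALSE]
  kept[kept == "H"] <- "."
  n_anc <- colSums(kept == "A")
  n_der <- colSums(kept == "D")
  monomorphic <- (n_anc == 0L) | (n_der == 0L)
  marker_qc <- data.frame(marker = colnames(calls),
                          n_ancestral = n_anc, n_derived = n_der,
                          monomorphic = monomorphic,
                          excluded = monomorphic,
                          stringsAsFactors = FALSE)
  calls[!excluded, ] <- kept
  new_genotype_matrix(calls, qc_applied = TRUE,
                      sample_qc = sample_qc, marker_qc = marker_qc)
}

qc_retained_samples <- function(genotypes) {
  if (isTRUE(genotypes$qc_applied))
    genotypes$sample_qc$sample_id[!genotypes$sample_qc$excluded]
  else genotypes$sample_ids
}

#' Markers retained for association after QC
#'
#' @param genotypes A QC'd `genotype_matrix`.
#' @return Character vector of polymorphic, retained marker names.
#' @export
analyzed_markers <- function(genotypes) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (!isTRUE(genotypes$qc_applied)) stop("apply_qc() first")
  genotypes$marker_qc$marker[!genotypes$marker_qc$excluded]
}

#' Average duplicate-sample concordance
#'
#' For each pair of duplicate samples, the fraction of jointly non-missing
#' calls that agree; the result is the unweighted average over pairs. Pairs
#' with no jointly called marker are dropped with a warning.
#'
#' @param genotypes A `genotype_matrix` (QC'd or raw; raw calls are used).
#' @param duplicate_pairs Data.frame (or 2-column matrix) of sample id
#'   pairs, one pair per row.
#' @return Numeric scalar in \[0, 1\]; `NaN` when no pair is usable.
#' @export
duplicate_concordance <- function(genotypes, duplicate_pairs) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  pairs <- as.matrix(duplicate_pairs)
  if (ncol(pairs) != 2L) stop("duplicate_pairs must have two columns")
  ids <- rownames(genotypes$calls)
  missing <- setdiff(c(pairs), ids)
  if (length(missing))
    stop("duplicate id(s) not genotyped: ", paste(missing, collapse = ", "))
  per_pair <- apply(pairs, 1L, function(p) {
    a <- genotypes$calls[p[1], ]
    b <- genotypes$calls[p[2], ]
    joint <- a != "." & b != "."
    if (!any(joint)) return(NA_real_)
    mean(a[joint] == b[joint])
  })
  if (anyNA(per_pair)) {
    warning(sum(is.na(per_pair)),
            " pair(s) with no jointly called marker dropped")
    per_pair <- per_pair[!is.na(per_pair)]
  }
  mean(per_pair)
}
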