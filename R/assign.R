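# From marker calls to per-branch carrier indicators and frequency tables.

#' Per-branch carrier status along the haplogroup tree
#'
#' Converts QC'd marker calls into a samples x branches matrix of derived
#' carrier indicators. For a typed branch, a man is a carrier when any of
#' its genotyped defining markers is derived and none is ancestral
#' (discordant phylogenetically equivalent markers give a missing status).
#' Tree consistency is then enforced: a derived call at a branch together
#' with an ancestral call at one of its ancestor branches is a conflict, and
#' both statuses are set missing — the conservative counterpart of treating
#' heterozygous Y calls as unreliable. Finally, untyped branches allowed by
#' [imputable_branches()] are filled: carrier iff carrier at the parent
#' (trivially true when the parent is the root) and non-carrier at every
#' sibling; non-carrier as soon as the parent is a non-carrier or any
#' sibling a carrier; missing otherwise.
#'
#' Samples excluded by [apply_qc()] contribute no rows.
#'
#' @param genotypes A QC'd `genotype_matrix` (see [apply_qc()]). All its
#'   markers must be attached to the tree.
#' @param tree A `haplo_tree`.
#' @return A `branch_carrier_matrix`: list with `status` (integer matrix,
#'   1 carrier / 0 non-carrier / NA missing, samples x branches),
#'   `provenance` (named character, `"typed"` or `"imputed"` per branch),
#'   `typed_branches`, `imputed_branches`, and `n_conflicts` (number of
#'   sample-branch statuses blanked by the consistency rule).
#' @export
branch_status <- function(genotypes, tree) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(tree, "haplo_tree"))
  if (!isTRUE(genotypes$qc_applied))
    stop("apply_qc() before branch_status()")
  markers <- genotypes$marker_names
  unknown <- setdiff(markers, tree$markers$name)
  if (length(unknown))
    stop("marker(s) in genotype matrix absent from tree: ",
         paste(unknown, collapse = ", "))

  keep <- qc_retained_samples(genotypes)
  calls <- genotypes$calls[keep, , drop = FALSE]
  typed <- typed_nodes(tree, markers)
  # preorder keeps ancestors before descendants in the status matrix
  typed <- intersect(tree_preorder(tree), typed)

  n <- nrow(calls)
  status <- matrix(NA_integer_, n, length(typed),
                   dimnames = list(rownames(calls), typed))
  for (b in typed) {
    mk <- intersect(tree$nodes[[b]]$markers, markers)
    sub <- calls[, mk, drop = FALSE]
    any_d <- rowSums(sub == "D") > 0L
    any_a <- rowSums(sub == "A") > 0L
    status[any_d & !any_a, b] <- 1L
    status[any_a & !any_d, b] <- 0L
    # both derived and ancestral among equivalent markers -> stays NA
  }

  n_conflicts <- 0L
  for (b in typed) {
    ancs <- intersect(tree_ancestors(tree, b), typed)
    for (a in ancs) {
      bad <- !is.na(status[, b]) & status[, b] == 1L &
             !is.na(status[, a]) & status[, a] == 0L
      if (any(bad)) {
        n_conflicts <- n_conflicts + 2L * sum(bad)
        status[bad, b] <- NA_integer_
        status[bad, a] <- NA_integer_
      }
    }
  }

  imp <- imputable_branches(tree, typed, recursive = TRUE)
  if (nrow(imp)) {
    add <- matrix(NA_integer_, n, nrow(imp),
                  dimnames = list(rownames(calls), imp$branch))
    status <- cbind(status, add)
    for (i in seq_len(nrow(imp))) {
      b <- imp$branch[i]
      p <- imp$parent[i]
      par <- if (is.na(p) || p == tree$root) rep(1L, n) else status[, p]
      sibs <- strsplit(imp$siblings[i], ";", fixed = TRUE)[[1]]
      sib_mat <- status[, sibs, drop = FALSE]
      any_sib_carrier <- rowSums(sib_mat == 1L, na.rm = TRUE) > 0L
      all_sib_clear <- rowSums(is.na(sib_mat) | sib_mat == 1L) == 0L
      st <- rep(NA_integer_, n)
      st[!is.na(par) & par == 0L] <- 0L
      st[any_sib_carrier & (is.na(st))] <- 0L
      st[!is.na(par) & par == 1L & all_sib_clear] <- 1L
      status[, b] <- st
    }
  }

  provenance <- setNames(
    c(rep("typed", length(typed)), rep("imputed", nrow(imp))),
    c(typed, imp$branch))
  structure(list(status = status,
                 sample_ids = rownames(calls),
                 provenance = provenance,
                 typed_branches = typed,
                 imputed_branches = imp$branch,
                 n_conflicts = n_conflicts,
                 tree = tree),
            class = "branch_carrier_matrix")
}

#' @export
print.branch_carrier_matrix <- function(x, ...) {
  cat("branch_carrier_matrix:", nrow(x$status), "samples x",
      ncol(x$status), "branches (", length(x$typed_branches), "typed,",
      length(x$imputed_branches), "imputed ),",
      x$n_conflicts, "statuses blanked by consistency\n")
  invisible(x)
}

#' Deepest carried haplogroup per sample
#'
#' @param carriers A `branch_carrier_matrix`.
#' @return Named character vector: for each sample the deepest branch with
#'   carrier status (the man's resolved haplogroup, possibly a paragroup
#'   when no deeper marker is derived); `NA` when no branch is carried.
#' @export
assigned_haplogroup <- function(carriers) {
  stopifnot(inherits(carriers, "branch_carrier_matrix"))
  depth <- vapply(colnames(carriers$status), function(b)
    length(tree_path(carriers$tree, b)), integer(1))
  ord <- order(depth, decreasing = TRUE)
  st <- carriers$status[, ord, drop = FALSE]
  labs <- colnames(st)
  apply(st, 1L, function(row) {
    hit <- which(!is.na(row) & row == 1L)
    if (length(hit)) labs[hit[1]] else NA_character_
  })
}

#' Derived-allele frequency tables by stratum
#'
#' Computes, for every branch and every stratum defined by the requested
#' record columns, the number of samples with a called (non-missing) status
#' and the derived carrier frequency among them.
#'
#' @param carriers A `branch_carrier_matrix`.
#' @param records Sample-record data.frame covering the carrier samples
#'   (extra records are ignored). Any column can be used for stratification,
#'   including columns the caller adds (e.g. a subgroup flag).
#' @param stratify_by Character vector of record column names; use
#'   `character(0)` for a single pooled stratum. Unknown columns are an
#'   error; empty strata are an error.
#' @param branches Branch labels to tabulate (default: all).
#' @return Data.frame with the stratum key columns plus `branch`,
#'   `n_called`, `n_derived`, `derived_freq`.
#' @export
haplogroup_frequencies <- function(carriers, records,
                                   stratify_by = "study",
                                   branches = NULL) {
  stopifnot(inherits(carriers, "branch_carrier_matrix"))
  unknown <- setdiff(stratify_by, names(records))
  if (length(unknown))
    stop("unknown stratification key(s): ", paste(unknown, collapse = ", "))
  idx <- match(carriers$sample_ids, records$sample_id)
  if (anyNA(idx))
    stop("record(s) missing for sample(s): ",
         paste(carriers$sample_ids[is.na(idx)], collapse = ", "))
  rec <- records[idx, , drop = FALSE]
  if (is.null(branches)) branches <- colnames(carriers$status)
  st <- carriers$status[, branches, drop = FALSE]

  if (length(stratify_by) == 0L) {
    key <- factor(rep("all", nrow(st)))
    keys_df <- data.frame(stratum = "all")
  } else {
    key <- interaction(rec[stratify_by], drop = TRUE, sep = "\r")
    keys_df <- do.call(rbind, strsplit(levels(key), "\r", fixed = TRUE))
    keys_df <- as.data.frame(keys_df, stringsAsFactors = FALSE)
    names(keys_df) <- stratify_by
  }
  if (nlevels(key) == 0L) stop("no non-empty strata")

  out <- lapply(seq_len(nlevels(key)), function(k) {
    rows <- key == levels(key)[k]
    sub <- st[rows, , drop = FALSE]
    n_called <- colSums(!is.na(sub))
    n_derived <- colSums(sub == 1L, na.rm = TRUE)
    cbind(keys_df[rep(k, length(branches)), , drop = FALSE],
          data.frame(branch = branches, n_called = unname(n_called),
                     n_derived = unname(n_derived),
                     derived_freq = unname(ifelse(n_called > 0,
                                                  n_derived / n_called,
                                                  NA_real_)),
                     stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Pool rare classes for frequency display
#'
#' Display companion to [haplogroup_frequencies()] for circle-plot style
#' summaries: within each stratum, classes below `min_freq` are pooled into
#' one residual class. Display only — the analysis set is never affected.
#'
#' @param freqs Output of [haplogroup_frequencies()].
#' @param min_freq Display threshold (default 0.05).
#' @param other_label Label for the pooled residual class.
#' @return Data.frame like `freqs` with rare rows collapsed.
#' @export
display_frequencies <- function(freqs, min_freq = 0.05,
                                other_label = "other") {
  keys <- setdiff(names(freqs),
                  c("branch", "n_called", "n_derived", "derived_freq"))
  split_key <- if (length(keys)) interaction(freqs[keys], drop = TRUE)
               else factor(rep(1, nrow(freqs)))
  out <- lapply(split(freqs, split_key), function(d) {
    small <- !is.na(d$derived_freq) & d$derived_freq < min_freq
    if (!any(small)) return(d)
    pooled <- d[which(small)[1], , drop = FALSE]
    pooled$branch <- other_label
    pooled$n_derived <- sum(d$n_derived[small])
    pooled$derived_freq <- sum(d$derived_freq[small])
    pooled$n_called <- NA_integer_
    rbind(d[!small, , drop = FALSE], pooled)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Disease-severity subgroup of each sample
#'
#' Cases are split by tumour grade and extent: aggressive when Gleason
#' score >= 7 or disease stage >= III (either alone suffices, so one known
#' qualifying value decides even if the other is missing); non-aggressive
#' when Gleason < 7 and stage < III (both must be known); otherwise the
#' case is unclassified. Controls are their own level.
#'
#' @param records Sample-record data.frame with `is_case`, `gleason`,
#'   `stage`.
#' @return Factor with levels `control`, `nonaggressive`, `aggressive`,
#'   `unclassified`, one per record row.
#' @export
classify_aggressiveness <- function(records) {
  g <- records$gleason
  s <- records$stage
  aggressive <- (!is.na(g) & g >= 7) | (!is.na(s) & s >= 3)
  nonaggr <- !is.na(g) & g < 7 & !is.na(s) & s < 3
  out <- rep("unclassified", nrow(records))
  out[aggressive] <- "aggressive"
  out[nonaggr] <- "nonaggressive"
  out[!records$is_case] <- "control"
  factor(out, levels = c("control", "nonaggressive", "aggressive",
                         "unclassified"))
}

#' Flag samples in the inferred Ashkenazi Jewish substructure cluster
#'
#' Principal-component coordinates from autosomal genotype PCA separate a
#' cluster consistent with Ashkenazi Jewish ancestry from the main
#' European-ancestry cloud: negative first eigenvector (EV1) together with
#' positive second eigenvector (EV2). The thresholds are configurable.
#'
#' @param records Sample-record data.frame with `ev1`, `ev2`.
#' @param ev1_max EV1 must be strictly below this (default 0).
#' @param ev2_min EV2 must be strictly above this (default 0).
#' @return Logical vector, `NA` where either coordinate is missing.
#' @export
classify_substructure <- function(records, ev1_max = 0, ev2_min = 0) {
  ifelse(is.na(records$ev1) | is.na(records$ev2), NA,
         records$ev1 < ev1_max & records$ev2 > ev2_min)
}
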