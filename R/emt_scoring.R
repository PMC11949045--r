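# Expression-derived scores: relative fold change, DEG threshold filtering,
# the epithelial/hEMT/mesenchymal trajectory score, and the IL6-correlated
# functional-category score.

#' Relative fold change against a reference mean
#'
#' `(sample_value - reference_mean) / reference_mean`: 0 at the reference
#' level, -1 when a non-negative quantity vanishes. This linear relative
#' fold change (not log2) is the scale on which the trajectory scores are
#' computed; see [fold_change_table()] for the matrix version with drop
#' reporting.
#'
#' @param sample_value Non-negative expression value(s).
#' @param reference_mean Positive reference mean (vectorized).
#' @return Numeric vector of relative fold changes.
#' @export
#' @examples
#' relative_fold_change(15, 10)  # 0.5
relative_fold_change <- function(sample_value, reference_mean) {
  if (any(reference_mean <= 0, na.rm = TRUE)) {
    stop("reference_mean must be positive; drop such genes upstream",
         call. = FALSE)
  }
  (sample_value - reference_mean) / reference_mean
}

#' Per-gene fold-change table between case and control samples
#'
#' Computes, for every gene, the relative fold change of the mean case
#' expression against the mean control expression. Genes whose control mean
#' is zero are dropped and reported rather than producing infinities.
#'
#' @param expr Genes x samples numeric matrix.
#' @param case_cols,control_cols Column names or indices of the two groups.
#' @param log2 Report `log2(case_mean / control_mean)` instead of the linear
#'   relative fold change.
#' @return Data frame with columns `gene`, `fold_change`; attribute
#'   `dropped` lists genes removed for a zero control mean.
#' @export
fold_change_table <- function(expr, case_cols, control_cols, log2 = FALSE) {
  case_mean <- rowMeans(expr[, case_cols, drop = FALSE])
  control_mean <- rowMeans(expr[, control_cols, drop = FALSE])
  keep <- control_mean > 0
  fc <- if (log2) {
    log2(case_mean[keep] / control_mean[keep])
  } else {
    relative_fold_change(case_mean[keep], control_mean[keep])
  }
  out <- data.frame(gene = rownames(expr)[keep], fold_change = unname(fc),
                    stringsAsFactors = FALSE)
  attr(out, "dropped") <- rownames(expr)[!keep]
  out
}

#' Threshold-filter differentially expressed genes
#'
#' Keeps genes with `adjusted_p < p_cut` and `|fold_change| > fc_cut`, both
#' strict. Genes with a missing adjusted p-value cannot pass the filter and
#' are dropped and reported.
#'
#' @param stats Data frame with columns `gene`, `fold_change`, and
#'   `adjusted_p`.
#' @param p_cut Adjusted p-value cutoff in `(0, 1]` (conventionally 0.01).
#' @param fc_cut Absolute fold-change cutoff (> 0), e.g. 1 or 0.5.
#' @return The surviving rows, with attributes `n_kept`, `n_dropped`,
#'   `n_missing_p`.
#' @export
filter_degs <- function(stats, p_cut = 0.01, fc_cut = 1) {
  if (!all(c("gene", "fold_change") %in% names(stats))) {
    stop("stats needs columns gene and fold_change", call. = FALSE)
  }
  if (p_cut <= 0 || p_cut > 1) stop("p_cut must be in (0, 1]", call. = FALSE)
  if (fc_cut <= 0) stop("fc_cut must be positive", call. = FALSE)
  if (!"adjusted_p" %in% names(stats)) {
    stop("stats lacks adjusted_p; p filtering requested", call. = FALSE)
  }
  missing_p <- is.na(stats$adjusted_p)
  keep <- !missing_p & stats$adjusted_p < p_cut &
    abs(stats$fold_change) > fc_cut
  out <- stats[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_kept") <- sum(keep)
  attr(out, "n_dropped") <- sum(!keep)
  attr(out, "n_missing_p") <- sum(missing_p)
  out
}

fc_lookup <- function(fold_changes) {
  if (is.data.frame(fold_changes)) {
    stats::setNames(fold_changes$fold_change, fold_changes$gene)
  } else if (!is.null(names(fold_changes))) {
    fold_changes
  } else {
    stop("fold_changes must be a named vector or a gene/fold_change table",
         call. = FALSE)
  }
}

#' EMT trajectory score
#'
#' Scores a sample's position along the epithelial / hybrid-EMT /
#' mesenchymal spectrum from per-gene fold changes and three curated gene
#' sets. The epithelial score is the mean fold change over epithelial genes;
#' the hEMT and mesenchymal scores are the corresponding category means with
#' the epithelial mean subtracted, so positive values indicate a shift away
#' from the epithelial program and values below 0 indicate underrepresented
#' gene groups. Genes absent from `fold_changes` are skipped and counted,
#' never imputed.
#'
#' @param fold_changes Named numeric vector of fold changes, or a data frame
#'   with columns `gene` and `fold_change`.
#' @param sets Named list with elements `epithelial`, `hEMT`, `mesenchymal`,
#'   each a character vector of gene identifiers (see
#'   [example_emt_gene_sets()]).
#' @return An `emt_score` list: `epithelial`, `hEMT`, `mesenchymal` (NA when
#'   no genes of a category are present, with a flag), `n_genes_used`
#'   (named integer vector), `flags`.
#' @export
#' @examples
#' fc <- c(E1 = 0.2, E2 = 0.4, H1 = 0.5, H2 = 0.7, M1 = 1.0)
#' sets <- list(epithelial = c("E1", "E2"), hEMT = c("H1", "H2"),
#'              mesenchymal = "M1")
#' emt_trajectory_score(fc, sets)
emt_trajectory_score <- function(fold_changes, sets) {
  needed <- c("epithelial", "hEMT", "mesenchymal")
  if (!all(needed %in% names(sets))) {
    stop("sets needs elements: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  fc <- fc_lookup(fold_changes)
  means <- numeric(3)
  names(means) <- needed
  n_used <- integer(3)
  names(n_used) <- needed
  flags <- character(0)
  for (cat in needed) {
    present <- intersect(sets[[cat]], names(fc))
    n_used[cat] <- length(present)
    if (length(present) == 0) {
      means[cat] <- NA_real_
      flags <- c(flags, paste0("no genes found for category: ", cat))
    } else {
      means[cat] <- mean(fc[present])
    }
  }
  structure(
    list(
      epithelial = unname(means["epithelial"]),
      hEMT = unname(means["hEMT"] - means["epithelial"]),
      mesenchymal = unname(means["mesenchymal"] - means["epithelial"]),
      n_genes_used = n_used,
      flags = flags
    ),
    class = "emt_score"
  )
}

#' @export
print.emt_score <- function(x, ...) {
  cat(sprintf("EMT trajectory score: epithelial %.4f, hEMT %.4f, mesenchymal %.4f\n",
              x$epithelial, x$hEMT, x$mesenchymal))
  if (length(x$flags) > 0) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' IL6-correlated gene score by functional category
#'
#' For each functional category of genes coexpressed with IL6 (inflammation,
#' metabolism, cell cycle control/apoptosis, motility/adhesion,
#' proliferation), averages each member gene's expression over replicates
#' and reports the summed case means minus the summed control means.
#' Positive scores therefore indicate the category is elevated in the case
#' group. Genes missing from either matrix are skipped and counted.
#'
#' @param expr_case,expr_control Genes x replicates numeric matrices.
#' @param category_sets Named list of gene identifier vectors, one per
#'   functional category (see [example_il6_gene_sets()]).
#' @return An `il6_score` list: `scores` (named numeric, NA for categories
#'   with no genes present), `n_genes_used`, `flags`.
#' @export
il6_gene_score <- function(expr_case, expr_control, category_sets) {
  if (length(category_sets) == 0) {
    stop("no categories supplied", call. = FALSE)
  }
  case_mean <- rowMeans(expr_case)
  control_mean <- rowMeans(expr_control)
  common <- intersect(names(case_mean), names(control_mean))
  scores <- numeric(length(category_sets))
  names(scores) <- names(category_sets)
  n_used <- integer(length(category_sets))
  names(n_used) <- names(category_sets)
  flags <- character(0)
  for (cat in names(category_sets)) {
    present <- intersect(category_sets[[cat]], common)
    n_used[cat] <- length(present)
    if (length(present) == 0) {
      scores[cat] <- NA_real_
      flags <- c(flags, paste0("no genes found for category: ", cat))
    } else {
      scores[cat] <- sum(case_mean[present]) - sum(control_mean[present])
    }
  }
  structure(list(scores = scores, n_genes_used = n_used, flags = flags),
            class = "il6_score")
}

#' @export
print.il6_score <- function(x, ...) {
  cat("IL6-correlated gene score (case - control):\n")
  for (nm in names(x$scores)) {
    cat(sprintf("  %-28s %10.2f (n = %d)\n", nm, x$scores[nm],
                x$n_genes_used[nm]))
  }
  invisible(x)
}

#' Illustrative EMT phenotype gene sets
#'
#' Small epithelial / hEMT / mesenchymal marker sets built from widely used
#' EMT marker genes. These are illustrative stand-ins for curated phenotype
#' lists: swap in your own sets (e.g. via [read_gmt()]) for real analyses.
#'
#' @return Named list of character vectors.
#' @export
example_emt_gene_sets <- function() {
  list(
    epithelial = c("CDH1", "EPCAM", "KRT8", "KRT18", "CLDN4", "CLDN7",
                   "OCLN", "DSP", "ESRP1", "GRHL2"),
    hEMT = c("KRT14", "KRT5", "P4HA2", "LAMC2", "ITGB4", "ITGB6",
             "SNAI1", "TNC", "VCAN", "PDPN"),
    mesenchymal = c("VIM", "CDH2", "FN1", "TWIST1", "SNAI2", "ZEB1",
                    "ZEB2", "MMP2", "S100A4", "FOXC2")
  )
}

#' Illustrative IL6-correlated functional category gene sets
#'
#' Stand-in gene lists for the five functional categories of genes
#' coexpressed with IL6 in high-grade serous ovarian cancer. Replace with a
#' curated list for real analyses.
#'
#' @return Named list of character vectors.
#' @export
example_il6_gene_sets <- function() {
  list(
    inflammation = c("IL6", "IL1B", "CXCL8", "CXCL1", "CCL2", "TNF",
                     "NFKB1", "PTGS2"),
    metabolism = c("HK2", "PFKP", "LDHA", "SLC2A1", "G6PD", "IDH1"),
    `cell cycle control/apoptosis` = c("CCND1", "CDKN1A", "BCL2L1", "MCL1",
                                       "BIRC3", "XIAP"),
    `motility/adhesion` = c("ICAM1", "ITGA5", "ITGB1", "MMP9", "PLAUR",
                            "CD44", "THBS1", "LAMB3"),
    proliferation = c("MKI67", "MYC", "CCNB1", "PCNA", "TOP2A", "E2F1")
  )
}
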