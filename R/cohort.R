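# Cohort-level analysis: APOBEC-high/low classification, paired
# primary/metastatic enrichment, survivor classes and survival summaries.

DAYS_PER_YEAR <- 365.25

#' Classify samples as APOBEC-high or APOBEC-low
#'
#' Labels a sample `high` when its APOBEC fraction (SBS2 + SBS13 relative
#' contribution) strictly exceeds the threshold. In `fixed` mode the
#' threshold is supplied (the cohort-derived cutoff of 0.04, i.e. >4%
#' relative contribution, is the conventional default); in `upper_quartile`
#' mode it is set to the 75th percentile of the input fractions, so with the
#' strict inequality at most a quarter of samples are labeled high and ties
#' at the quartile fall to `low`.
#'
#' @param fractions Numeric vector of APOBEC fractions in `[0, 1]`.
#' @param mode `"fixed"` or `"upper_quartile"`.
#' @param threshold Required in `fixed` mode.
#' @return List with `labels` (character, `"high"`/`"low"`, `NA` fractions
#'   propagate) and `threshold_used`.
#' @export
#' @examples
#' classify_apobec(c(0.01, 0.02, 0.05, 0.10), "fixed", 0.04)
classify_apobec <- function(fractions, mode = c("fixed", "upper_quartile"),
                            threshold = NULL) {
  mode <- match.arg(mode)
  if (length(fractions) == 0) stop("no fractions supplied", call. = FALSE)
  ok <- !is.na(fractions)
  if (any(fractions[ok] < 0 | fractions[ok] > 1)) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  threshold_used <- if (mode == "fixed") {
    if (is.null(threshold)) {
      stop("fixed mode requires a threshold", call. = FALSE)
    }
    threshold
  } else {
    unname(stats::quantile(fractions, 0.75, na.rm = TRUE))
  }
  labels <- ifelse(is.na(fractions), NA_character_,
                   ifelse(fractions > threshold_used, "high", "low"))
  list(labels = labels, threshold_used = threshold_used)
}

#' Paired primary-metastatic APOBEC enrichment
#'
#' For each patient with both a primary and a metastatic sample, reports the
#' metastatic/primary APOBEC-fraction ratio; patients with a zero primary
#' fraction get an undefined (NA) per-patient ratio. The pooled ratio is the
#' sum of metastatic fractions over the sum of primary fractions across all
#' complete pairs (zero-primary patients included), mirroring a pooled
#' comparison of all primary versus all metastatic samples.
#'
#' @param cohort Data frame with columns `patient_id`, `site`
#'   (`"primary"`/`"metastatic"`), `apobec_fraction`.
#' @return List with `per_patient` (data frame: `patient_id`, `primary`,
#'   `metastatic`, `ratio`), `pooled_ratio`, and `geometric_mean_ratio` over
#'   patients with a defined ratio.
#' @export
paired_enrichment <- function(cohort) {
  needed <- c("patient_id", "site", "apobec_fraction")
  if (!all(needed %in% names(cohort))) {
    stop("cohort needs columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  prim <- cohort[cohort$site == "primary", ]
  met <- cohort[cohort$site == "metastatic", ]
  patients <- intersect(unique(prim$patient_id), unique(met$patient_id))
  if (length(patients) == 0) {
    stop("no complete primary/metastatic pairs", call. = FALSE)
  }
  p_frac <- vapply(patients, function(p) {
    mean(prim$apobec_fraction[prim$patient_id == p])
  }, numeric(1))
  m_frac <- vapply(patients, function(p) {
    mean(met$apobec_fraction[met$patient_id == p])
  }, numeric(1))
  ratio <- ifelse(p_frac > 0, m_frac / p_frac, NA_real_)
  per_patient <- data.frame(
    patient_id = patients, primary = p_frac, metastatic = m_frac,
    ratio = ratio, stringsAsFactors = FALSE
  )
  defined <- ratio[!is.na(ratio) & ratio > 0]
  list(
    per_patient = per_patient,
    pooled_ratio = sum(m_frac) / sum(p_frac),
    geometric_mean_ratio = if (length(defined) > 0) {
      exp(mean(log(defined)))
    } else {
      NA_real_
    }
  )
}

#' Short/long/intermediate survivor classes
#'
#' Classifies overall survival using strict cuts: `short` below
#' `short_cut_years`, `long` above `long_cut_years`, `intermediate` in
#' between; a year is 365.25 days. Missing survival yields `NA`.
#'
#' @param survival_days Positive survival times in days.
#' @param short_cut_years,long_cut_years Class cuts in years (defaults 3.5
#'   and 5).
#' @return Character vector in `{"short", "intermediate", "long"}`.
#' @export
#' @examples
#' survivor_class(c(730, 1500, 2200))
survivor_class <- function(survival_days, short_cut_years = 3.5,
                           long_cut_years = 5) {
  if (short_cut_years >= long_cut_years) {
    stop("short cut must be below long cut", call. = FALSE)
  }
  ok <- !is.na(survival_days)
  if (any(survival_days[ok] <= 0)) {
    stop("survival_days must be positive", call. = FALSE)
  }
  short_cut <- short_cut_years * DAYS_PER_YEAR
  long_cut <- long_cut_years * DAYS_PER_YEAR
  ifelse(!ok, NA_character_,
         ifelse(survival_days < short_cut, "short",
                ifelse(survival_days > long_cut, "long", "intermediate")))
}

#' Survival summary by APOBEC label
#'
#' Arithmetic mean survival per label with a two-sided unequal-variance
#' (Welch) location test between the `high` and `low` groups. The test is
#' reported only; labels are never revised from it.
#'
#' @param survival_days Numeric survival times (days); `NA` dropped.
#' @param labels Character labels (`"high"`/`"low"`), parallel to
#'   `survival_days`.
#' @return List with `summary` (data frame: `label`, `n`, `mean_days`),
#'   `difference_of_means` (high minus low), `p_value` (Welch t-test, `NA`
#'   when either group has fewer than 2 observations), and `flags` noting an
#'   absent group.
#' @export
group_survival_summary <- function(survival_days, labels) {
  keep <- !is.na(survival_days) & !is.na(labels)
  survival_days <- survival_days[keep]
  labels <- labels[keep]
  if (length(survival_days) == 0) {
    stop("no samples with survival and label", call. = FALSE)
  }
  groups <- split(survival_days, labels)
  summ <- data.frame(
    label = names(groups),
    n = vapply(groups, length, integer(1)),
    mean_days = vapply(groups, mean, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  flags <- character(0)
  for (lab in c("high", "low")) {
    if (!lab %in% names(groups)) {
      flags <- c(flags, paste0("group absent: ", lab))
    }
  }
  diff_means <- NA_real_
  p <- NA_real_
  if (all(c("high", "low") %in% names(groups))) {
    diff_means <- mean(groups$high) - mean(groups$low)
    if (length(groups$high) >= 2 && length(groups$low) >= 2) {
      p <- stats::t.test(groups$high, groups$low, var.equal = FALSE)$p.value
    } else {
      flags <- c(flags, "fewer than 2 observations in a group; no test")
    }
  }
  list(summary = summ, difference_of_means = diff_means, p_value = p,
       flags = flags)
}

#' Exact association test on a 2 x 2 table
#'
#' Fisher's exact (hypergeometric) test, two-sided and uncorrected, with the
#' sample odds ratio; when any cell is zero the Haldane correction (0.5
#' added to every cell) is applied to the odds ratio. A table with a zero
#' margin carries no information: p = 1 and the odds ratio is undefined.
#'
#' @param table 2 x 2 matrix of non-negative integer counts.
#' @return List with `odds_ratio`, `p_value`, `haldane` (logical),
#'   `degenerate` (zero-margin flag).
#' @export
#' @examples
#' association_test(matrix(c(10, 0, 0, 10), 2))
association_test <- function(table) {
  m <- as.matrix(table)
  if (!all(dim(m) == c(2L, 2L))) stop("need a 2 x 2 table", call. = FALSE)
  if (any(m < 0) || any(m != round(m))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  degenerate <- any(rowSums(m) == 0) || any(colSums(m) == 0)
  if (degenerate) {
    return(list(odds_ratio = NA_real_, p_value = 1, haldane = FALSE,
                degenerate = TRUE))
  }
  p <- stats::fisher.test(m)$p.value
  haldane <- any(m == 0)
  mm <- if (haldane) m + 0.5 else m
  or <- (mm[1, 1] * mm[2, 2]) / (mm[1, 2] * mm[2, 1])
  list(odds_ratio = or, p_value = p, haldane = haldane, degenerate = FALSE)
}

#' Assemble and annotate a cohort table
#'
#' Builds the per-sample cohort table: classifies APOBEC labels from the
#' fractions (by default on metastatic samples, with each patient's label
#' taken from their metastatic sample) and derives survivor classes from
#' survival times.
#'
#' @param cohort Data frame with columns `sample_id`, `patient_id`, `site`,
#'   `apobec_fraction`, and optionally `survival_days`.
#' @param mode,threshold Passed to [classify_apobec()].
#' @param label_site Site whose fractions define the threshold population
#'   and patient labels (default `"metastatic"`); use `NULL` to classify
#'   every sample from its own fraction against a threshold derived from all
#'   samples.
#' @return The cohort data frame with `apobec_label` and `survivor_class`
#'   columns added, plus attribute `threshold_used`.
#' @export
annotate_cohort <- function(cohort, mode = c("fixed", "upper_quartile"),
                            threshold = NULL, label_site = "metastatic") {
  mode <- match.arg(mode)
  if (is.null(label_site)) {
    cls <- classify_apobec(cohort$apobec_fraction, mode, threshold)
    cohort$apobec_label <- cls$labels
  } else {
    sel <- cohort$site == label_site
    if (!any(sel)) stop("no samples at site '", label_site, "'",
                        call. = FALSE)
    cls <- classify_apobec(cohort$apobec_fraction[sel], mode, threshold)
    by_patient <- stats::setNames(cls$labels, cohort$patient_id[sel])
    cohort$apobec_label <- unname(by_patient[as.character(cohort$patient_id)])
  }
  cohort$survivor_class <- if ("survival_days" %in% names(cohort)) {
    survivor_class(cohort$survival_days)
  } else {
    NA_character_
  }
  attr(cohort, "threshold_used") <- cls$threshold_used
  cohort
}
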