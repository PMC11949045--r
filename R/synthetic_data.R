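# Seeded synthetic-data generators: reference sequences, signature-mixture
# variant sets, paired primary/metastatic cohorts with planted APOBEC
# enrichment and survival structure, and overdispersed expression matrices
# with planted gene-set shifts. Every generated record carries its
# generating truth; truth fields are recorded at generation time, never
# inferred back from the data.

#' Generate a random reference sequence
#'
#' Draws i.i.d. bases with P(G) = P(C) = `gc_fraction / 2` and
#' P(A) = P(T) = `(1 - gc_fraction) / 2`, split into `n_contigs` contigs of
#' near-equal length (lengths partition `total_length`).
#'
#' @param total_length Total bases across contigs (>= 3 per contig).
#' @param gc_fraction Target GC proportion in `[0, 1]`.
#' @param n_contigs Number of contigs.
#' @param seed Integer seed; output is deterministic given all arguments.
#' @return A `synthetic_reference` list: `contigs` (named character vector,
#'   `chr1`, `chr2`, ...) and `gc_fraction`.
#' @export
#' @examples
#' ref <- make_reference(1000, 0.41, 1, seed = 1)
make_reference <- function(total_length, gc_fraction, n_contigs = 1L,
                           seed = 1L) {
  if (total_length <= 0 || n_contigs <= 0) {
    stop("total_length and n_contigs must be positive", call. = FALSE)
  }
  if (total_length < 3L * n_contigs) {
    stop("need at least 3 bases per contig", call. = FALSE)
  }
  if (gc_fraction < 0 || gc_fraction > 1) {
    stop("gc_fraction must lie in [0, 1]", call. = FALSE)
  }
  set.seed(seed)
  base_len <- total_length %/% n_contigs
  lens <- rep(base_len, n_contigs)
  extra <- total_length - sum(lens)
  if (extra > 0) lens[seq_len(extra)] <- lens[seq_len(extra)] + 1L
  probs <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
             G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  contigs <- vapply(lens, function(L) {
    paste(sample(DNA_BASES, L, replace = TRUE, prob = probs), collapse = "")
  }, character(1))
  names(contigs) <- paste0("chr", seq_len(n_contigs))
  structure(list(contigs = contigs, gc_fraction = gc_fraction),
            class = "synthetic_reference")
}

#' @export
print.synthetic_reference <- function(x, ...) {
  cat("synthetic reference: ", length(x$contigs), " contig(s), ",
      sum(nchar(x$contigs)), " bp, target GC ", x$gc_fraction, "\n", sep = "")
  invisible(x)
}

# Precompute, for each of the 32 pyrimidine-normalized trinucleotide
# contexts, the genomic positions realizing it (either strand). Columns:
# contig index, position; strand is implied by the center base at that
# position (pyrimidine = plus).
build_context_index <- function(reference) {
  seqs <- as_reference_seqs(reference)
  ctx_names <- unique(channel_context()$context)
  index <- stats::setNames(vector("list", length(ctx_names)), ctx_names)
  for (ci in seq_along(seqs)) {
    s <- seqs[[ci]]
    L <- nchar(s)
    if (L < 3L) next
    pos <- 2:(L - 1L)
    tri <- substring(s, pos - 1L, pos + 1L)
    keep <- !grepl("[^ACGT]", tri)
    pos <- pos[keep]
    tri <- tri[keep]
    center <- substr(tri, 2L, 2L)
    pur <- center %in% c("A", "G")
    tri[pur] <- revcomp(tri[pur])
    groups <- split(pos, tri)
    for (nm in names(groups)) {
      if (nm %in% ctx_names) {
        index[[nm]] <- rbind(index[[nm]],
                             cbind(contig = ci, pos = groups[[nm]]))
      }
    }
  }
  attr(index, "contig_names") <- names(seqs)
  index
}

#' Sample variants from a 96-channel signature
#'
#' Draws `n` single-nucleotide variants whose pyrimidine-normalized channels
#' follow the given signature: the channel is drawn first (multinomial over
#' the 96 channels), then a genomic position is chosen uniformly among all
#' positions matching the channel's trinucleotide context on either strand,
#' which guarantees that rebuilding the catalog from the variants reproduces
#' the drawn channels exactly. Channels with no genomic support are removed
#' and the signature renormalized over the supported channels.
#'
#' @param reference Reference sequences (see [extract_context()]).
#' @param signature Probability vector over the 96 channels (named by
#'   channel or in [sbs_channels()] order), summing to 1.
#' @param n Number of variants (>= 1).
#' @param seed Integer seed.
#' @param sample_id Sample label for the output rows.
#' @param context_index Optional precomputed [build_context_index()] of
#'   `reference`; pass it when drawing many samples from one reference.
#' @return Variant data frame (`sample_id`, `chrom`, `pos`, `ref`, `alt`)
#'   with a `channel` column recording each variant's generating truth
#'   channel.
#' @export
sample_variants <- function(reference, signature, n, seed = 1L,
                            sample_id = "S1", context_index = NULL) {
  if (n < 1L) stop("n must be a positive integer", call. = FALSE)
  channels <- sbs_channels()
  sig <- as.numeric(signature)
  if (length(sig) != 96L) stop("signature must have 96 entries", call. = FALSE)
  if (!is.null(names(signature))) {
    if (!setequal(names(signature), channels)) {
      stop("signature names must be the 96 standard channels", call. = FALSE)
    }
    sig <- as.numeric(signature[channels])
  }
  if (any(sig < 0) || abs(sum(sig) - 1) > 1e-6) {
    stop("signature must be non-negative and sum to 1", call. = FALSE)
  }
  seqs <- as_reference_seqs(reference)
  index <- if (is.null(context_index)) build_context_index(seqs) else
    context_index
  meta <- channel_context(channels)
  supported <- vapply(meta$context,
                      function(cx) !is.null(index[[cx]]), logical(1))
  sig[!supported] <- 0
  if (sum(sig) == 0) {
    stop("no genomic position supports any positive-probability channel",
         call. = FALSE)
  }
  sig <- sig / sum(sig)
  set.seed(seed)
  counts <- as.vector(stats::rmultinom(1, n, sig))
  rows <- vector("list", sum(counts > 0))
  ri <- 1L
  for (k in which(counts > 0)) {
    idx <- index[[meta$context[k]]]
    pick <- idx[sample.int(nrow(idx), counts[k], replace = TRUE), ,
                drop = FALSE]
    chrom <- names(seqs)[pick[, "contig"]]
    pos <- pick[, "pos"]
    ref <- substr(seqs[chrom], pos, pos)
    alt_pyr <- substr(meta$class[k], 3L, 3L)
    minus <- ref %in% c("A", "G")
    alt <- ifelse(minus, complement_base(alt_pyr), alt_pyr)
    rows[[ri]] <- data.frame(
      sample_id = sample_id, chrom = chrom, pos = as.integer(pos),
      ref = ref, alt = alt, channel = channels[k],
      stringsAsFactors = FALSE
    )
    ri <- ri + 1L
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sample APOBEC-context variants with a fixed enzyme preference
#'
#' Generates C>T / C>G mutations at TCA trinucleotides restricted to a
#' chosen tetranucleotide class: `"A3A"` places every mutation at a YTCA
#' context (pyrimidine 5' of the TpC), `"A3B"` at RTCA, and `"uniform"` at
#' any TCA site regardless of the 5' base. Used to plant
#' enzyme-attributable mutagenesis with known truth.
#'
#' @param reference Reference sequences.
#' @param n Number of variants.
#' @param enzyme `"A3A"`, `"A3B"`, or `"uniform"`.
#' @param ct_fraction Fraction of C>T among the mutations (remainder C>G).
#' @param seed Integer seed.
#' @param sample_id Sample label.
#' @return Variant data frame with a truth `enzyme` column.
#' @export
sample_apobec_variants <- function(reference, n,
                                   enzyme = c("A3A", "A3B", "uniform"),
                                   ct_fraction = 0.5, seed = 1L,
                                   sample_id = "S1") {
  enzyme <- match.arg(enzyme)
  if (n < 1L) stop("n must be a positive integer", call. = FALSE)
  seqs <- as_reference_seqs(reference)
  sites <- apobec_tca_sites(seqs)
  want <- switch(enzyme,
                 A3A = sites[sites$fifth %in% c("C", "T"), , drop = FALSE],
                 A3B = sites[sites$fifth %in% c("A", "G"), , drop = FALSE],
                 uniform = sites)
  if (nrow(want) == 0) {
    stop("reference contains no qualifying TCA site for enzyme ", enzyme,
         call. = FALSE)
  }
  set.seed(seed)
  pick <- want[sample.int(nrow(want), n, replace = TRUE), , drop = FALSE]
  is_ct <- stats::runif(n) < ct_fraction
  alt_pyr <- ifelse(is_ct, "T", "G")
  alt <- ifelse(pick$strand == "+", alt_pyr, complement_base(alt_pyr))
  data.frame(
    sample_id = sample_id, chrom = pick$chrom, pos = pick$pos,
    ref = pick$ref, alt = alt, enzyme = enzyme,
    stringsAsFactors = FALSE
  )
}

# all genomic TCA sites (either strand) with their pyrimidine-orientation
# 5' tetranucleotide base; only sites where that base exists are returned
apobec_tca_sites <- function(seqs) {
  out <- NULL
  for (cn in names(seqs)) {
    s <- seqs[[cn]]
    L <- nchar(s)
    if (L < 4L) next
    # plus strand: T C A with C at p, need base at p - 2
    p <- 3:(L - 1L)
    tri <- substring(s, p - 1L, p + 1L)
    hit <- tri == "TCA"
    if (any(hit)) {
      pp <- p[hit]
      out <- rbind(out, data.frame(
        chrom = cn, pos = pp, ref = "C", strand = "+",
        fifth = substring(s, pp - 2L, pp - 2L), stringsAsFactors = FALSE))
    }
    # minus strand: plus-strand TGA with G at p (revcomp TCA), 5' base is
    # the complement of the base at p + 2
    p <- 2:(L - 2L)
    tri <- substring(s, p - 1L, p + 1L)
    hit <- tri == "TGA"
    if (any(hit)) {
      pp <- p[hit]
      out <- rbind(out, data.frame(
        chrom = cn, pos = pp, ref = "G", strand = "-",
        fifth = complement_base(substring(s, pp + 2L, pp + 2L)),
        stringsAsFactors = FALSE))
    }
  }
  if (is.null(out)) {
    data.frame(chrom = character(), pos = integer(), ref = character(),
               strand = character(), fifth = character(),
               stringsAsFactors = FALSE)
  } else {
    out
  }
}

#' Simulate a paired primary/metastatic cohort with planted enrichment
#'
#' Builds, per patient, a primary and a metastatic variant set drawn from
#' mixtures of the supplied signatures. The APOBEC weight (split equally
#' between the designated APOBEC pair) is `base_apobec` in the primary
#' sample and `min(1, base_apobec * met_fold)` in the metastatic sample
#' (clamped weights are flagged), with the remaining mass spread equally
#' over the background signatures. Survival is drawn from a normal model
#' conditioned on the truth label (metastatic APOBEC weight strictly above
#' `threshold`), floored at 1 day.
#'
#' @param n_patients Number of patients.
#' @param base_apobec Primary-site APOBEC weight in `[0, 1]`.
#' @param met_fold Planted metastatic/primary APOBEC weight ratio (> 0).
#' @param signatures 96 x k signature probability matrix containing the
#'   APOBEC pair (default [reference_signatures()]).
#' @param apobec_names The APOBEC-like signature pair (default SBS2/SBS13).
#' @param n_mutations Mutations per sample (default 5000).
#' @param survival_model List with `mean_days_high`, `mean_days_low`, `sd`.
#' @param threshold APOBEC-high truth threshold on the metastatic weight
#'   (default 0.04).
#' @param reference Optional reference; by default a 100 kb, GC 0.41
#'   single-contig reference is generated from the same seed.
#' @param seed Integer seed controlling every draw.
#' @return List with `variants` (all samples stacked; sample ids
#'   `P<i>_primary` / `P<i>_metastatic`) and `truth` (one row per sample:
#'   `sample_id`, `patient_id`, `site`, `apobec_weight`, `clamped`,
#'   `survival_days`, `apobec_label_truth`, `survivor_class_truth`), plus
#'   the `reference` used.
#' @export
simulate_cohort <- function(n_patients, base_apobec, met_fold,
                            signatures = reference_signatures(),
                            apobec_names = c("SBS2", "SBS13"),
                            n_mutations = 5000L,
                            survival_model = list(mean_days_high = 816.7,
                                                  mean_days_low = 1655.3,
                                                  sd = 200),
                            threshold = 0.04,
                            reference = NULL,
                            seed = 1L) {
  sig <- validate_signature_matrix(signatures)
  if (!all(apobec_names %in% colnames(sig))) {
    stop("signatures must contain the APOBEC pair: ",
         paste(apobec_names, collapse = ", "), call. = FALSE)
  }
  if (ncol(sig) <= length(apobec_names)) {
    stop("need at least one background signature besides the APOBEC pair",
         call. = FALSE)
  }
  if (met_fold <= 0) stop("met_fold must be positive", call. = FALSE)
  if (base_apobec < 0 || base_apobec > 1) {
    stop("base_apobec must lie in [0, 1]", call. = FALSE)
  }
  set.seed(seed)
  if (is.null(reference)) {
    reference <- make_reference(100000L, 0.41, 1L,
                                seed = sample.int(2^30, 1))
  }
  bg_names <- setdiff(colnames(sig), apobec_names)
  w_primary <- base_apobec
  w_met <- min(1, base_apobec * met_fold)
  clamped <- base_apobec * met_fold > 1

  mixture_probs <- function(w_apobec) {
    w <- stats::setNames(numeric(ncol(sig)), colnames(sig))
    w[apobec_names] <- w_apobec / length(apobec_names)
    w[bg_names] <- (1 - w_apobec) / length(bg_names)
    as.vector(sig %*% w)
  }

  label <- if (w_met > threshold) "high" else "low"
  mu <- if (label == "high") survival_model$mean_days_high else
    survival_model$mean_days_low

  ctx_index <- build_context_index(reference)
  variant_sets <- vector("list", 2L * n_patients)
  truth_rows <- vector("list", 2L * n_patients)
  ti <- 1L
  for (i in seq_len(n_patients)) {
    patient <- sprintf("P%02d", i)
    survival <- max(1, stats::rnorm(1, mu, survival_model$sd))
    for (site in c("primary", "metastatic")) {
      w <- if (site == "primary") w_primary else w_met
      sid <- paste0(patient, "_", site)
      probs <- mixture_probs(w)
      probs <- stats::setNames(probs, rownames(sig))
      variant_sets[[ti]] <- sample_variants(
        reference, probs, n_mutations,
        seed = sample.int(2^30, 1), sample_id = sid,
        context_index = ctx_index)
      truth_rows[[ti]] <- data.frame(
        sample_id = sid, patient_id = patient, site = site,
        apobec_weight = w, met_fold = met_fold,
        clamped = site == "metastatic" && clamped,
        survival_days = survival,
        apobec_label_truth = label,
        survivor_class_truth = survivor_class(survival),
        stringsAsFactors = FALSE
      )
      ti <- ti + 1L
    }
  }
  list(
    variants = do.call(rbind, variant_sets),
    truth = do.call(rbind, truth_rows),
    reference = reference
  )
}

#' Simulate an overdispersed expression matrix with planted shifts
#'
#' Draws gamma-Poisson (negative binomial) counts with a common base mean
#' and dispersion; genes belonging to the named effect sets have their case
#' group mean multiplied by the set's fold. With `dispersion = 0` the
#' counts are Poisson.
#'
#' @param n_genes Size of the gene universe. Member genes of `gene_sets`
#'   come first; the universe is padded with filler genes `G0001`, ... up to
#'   `n_genes`.
#' @param n_case,n_control Samples per group.
#' @param gene_sets Named list of gene identifier vectors.
#' @param effects Named list/vector mapping set name to a multiplicative
#'   case-group fold (> 0). Every name must be a name of `gene_sets`.
#' @param base_mean Mean count of unshifted genes (default 100).
#' @param dispersion Negative-binomial dispersion: variance is
#'   `mu + dispersion * mu^2` (default 0.1).
#' @param seed Integer seed.
#' @return A `planted_expression` list: `matrix` (genes x samples; case
#'   columns `case_1`, ..., control columns `control_1`, ...),
#'   `group_labels`, `effect_table`, `dispersion`.
#' @export
simulate_expression <- function(n_genes, n_case, n_control,
                                gene_sets = example_emt_gene_sets(),
                                effects = list(), base_mean = 100,
                                dispersion = 0.1, seed = 1L) {
  if (base_mean <= 0) stop("base_mean must be positive", call. = FALSE)
  if (dispersion < 0) stop("dispersion must be >= 0", call. = FALSE)
  universe <- unique(unlist(gene_sets, use.names = FALSE))
  if (length(universe) > n_genes) {
    stop("n_genes smaller than the union of gene_sets", call. = FALSE)
  }
  n_fill <- n_genes - length(universe)
  if (n_fill > 0) {
    universe <- c(universe, sprintf("G%04d", seq_len(n_fill)))
  }
  effects <- unlist(effects)
  unknown <- setdiff(names(effects), names(gene_sets))
  if (length(unknown) > 0) {
    stop("effect(s) reference unknown gene set(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (any(effects <= 0)) stop("effect folds must be positive", call. = FALSE)

  mu_control <- rep(base_mean, length(universe))
  mu_case <- mu_control
  for (nm in names(effects)) {
    members <- match(gene_sets[[nm]], universe)
    mu_case[members] <- mu_case[members] * effects[[nm]]
  }
  set.seed(seed)
  draw <- function(mu, n_samp) {
    n_tot <- length(mu) * n_samp
    if (dispersion > 0) {
      matrix(stats::rnbinom(n_tot, mu = rep(mu, n_samp),
                            size = 1 / dispersion),
             nrow = length(mu))
    } else {
      matrix(stats::rpois(n_tot, rep(mu, n_samp)), nrow = length(mu))
    }
  }
  m_case <- draw(mu_case, n_case)
  m_control <- draw(mu_control, n_control)
  m <- cbind(m_case, m_control)
  rownames(m) <- universe
  colnames(m) <- c(paste0("case_", seq_len(n_case)),
                   paste0("control_", seq_len(n_control)))
  structure(
    list(
      matrix = m,
      group_labels = c(rep("case", n_case), rep("control", n_control)),
      effect_table = effects,
      dispersion = dispersion
    ),
    class = "planted_expression"
  )
}

#' @export
print.planted_expression <- function(x, ...) {
  cat("planted expression matrix: ", nrow(x$matrix), " genes x ",
      ncol(x$matrix), " samples (", sum(x$group_labels == "case"),
      " case / ", sum(x$group_labels == "control"), " control)\n", sep = "")
  if (length(x$effect_table) > 0) {
    cat("planted effects:",
        paste(names(x$effect_table), x$effect_table, sep = " x",
              collapse = ", "), "\n")
  }
  invisible(x)
}
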