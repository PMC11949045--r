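# APOBEC3A vs APOBEC3B attribution from the tetranucleotide context of
# mutated cytosines. A3A preferentially deaminates cytosine in a YTCA
# context (Y = C or T), A3B in an RTCA context (R = A or G); the base 5' of
# the TpC dinucleotide therefore separates the two enzymes.

#' Count YTCA/RTCA contexts of APOBEC-context mutations
#'
#' A mutation qualifies when, after pyrimidine normalization, it is a C>T or
#' C>G substitution at a T-C-A trinucleotide (the substitution composition of
#' the APOBEC3 signatures SBS2 and SBS13). The base immediately 5' of that T
#' classifies the 4-mer as YTCA (Y = C/T), RTCA (R = A/G), or neither when it
#' is ambiguous or off the contig end. Background tetranucleotide
#' frequencies are computed by sliding a 4-mer window over both strands of
#' the reference, so a context and its reverse complement are counted once
#' per strand (double-strand-collapsed frequencies).
#'
#' @param variants Variant table (`sample_id`, `chrom`, `pos`, `ref`, `alt`).
#' @param reference Reference sequences (see [extract_context()]).
#' @return A `tetra_context_counts` list: `ytca`, `rtca`, `other_tca`
#'   (qualifying TCA mutations with unresolvable 5' base), `n_qualifying`,
#'   and background frequencies `background_ytca_freq`,
#'   `background_rtca_freq`.
#' @export
count_tca_contexts <- function(variants, reference) {
  seqs <- as_reference_seqs(reference)
  if (length(seqs) == 0 || all(!nzchar(seqs))) {
    stop("empty reference", call. = FALSE)
  }
  variants <- validate_variants(variants)

  ytca <- 0L
  rtca <- 0L
  other <- 0L
  n <- nrow(variants)
  if (n > 0) {
    known <- variants$chrom %in% names(seqs)
    v <- variants[known, , drop = FALSE]
    lens <- nchar(seqs)[v$chrom]
    in_tri <- v$pos >= 2L & v$pos <= lens - 1L
    v <- v[in_tri, , drop = FALSE]
    lens <- lens[in_tri]
    if (nrow(v) > 0) {
      tri <- substr(seqs[v$chrom], v$pos - 1L, v$pos + 1L)
      valid <- !grepl("[^ACGT]", tri) & substr(tri, 2L, 2L) == v$ref &
        v$ref != v$alt & v$alt %in% DNA_BASES
      v <- v[valid, , drop = FALSE]
      tri <- tri[valid]
      lens <- lens[valid]
      if (nrow(v) > 0) {
        norm <- pyrimidine_normalize(v$ref, v$alt, tri)
        qual <- norm$context == "TCA" & norm$class %in% c("C>T", "C>G")
        v <- v[qual, , drop = FALSE]
        lens <- lens[qual]
        plus <- v$ref == "C"   # pyrimidine already on the plus strand
        if (nrow(v) > 0) {
          # base 5' of the T in pyrimidine orientation: two bases 5' of the
          # mutated C on the plus strand, or the complement of the base two
          # 3' of it on the minus strand
          fifth <- rep(NA_character_, nrow(v))
          ok_plus <- plus & v$pos >= 3L
          fifth[ok_plus] <- substr(seqs[v$chrom[ok_plus]],
                                   v$pos[ok_plus] - 2L, v$pos[ok_plus] - 2L)
          ok_minus <- !plus & v$pos <= lens - 2L
          fifth[ok_minus] <- complement_base(
            substr(seqs[v$chrom[ok_minus]],
                   v$pos[ok_minus] + 2L, v$pos[ok_minus] + 2L))
          ytca <- sum(fifth %in% c("C", "T"), na.rm = TRUE)
          rtca <- sum(fifth %in% c("A", "G"), na.rm = TRUE)
          other <- nrow(v) - ytca - rtca
        }
      }
    }
  }

  bg <- tetranucleotide_background(seqs)
  structure(
    list(ytca = as.integer(ytca), rtca = as.integer(rtca),
         other_tca = as.integer(other),
         n_qualifying = as.integer(ytca + rtca + other),
         background_ytca_freq = bg[["ytca"]],
         background_rtca_freq = bg[["rtca"]]),
    class = "tetra_context_counts"
  )
}

# double-strand-collapsed 4-mer frequencies of YTCA and RTCA
tetranucleotide_background <- function(seqs) {
  sets <- Biostrings::DNAStringSet(seqs)
  fwd <- colSums(Biostrings::oligonucleotideFrequency(sets, width = 4L))
  rev <- colSums(Biostrings::oligonucleotideFrequency(
    Biostrings::reverseComplement(sets), width = 4L))
  both <- fwd + rev
  total <- sum(both)
  if (total == 0) {
    stop("reference too short to hold any tetranucleotide", call. = FALSE)
  }
  c(
    ytca = sum(both[c("CTCA", "TTCA")]) / total,
    rtca = sum(both[c("ATCA", "GTCA")]) / total
  )
}

#' @export
print.tetra_context_counts <- function(x, ...) {
  cat("YTCA/RTCA context counts: ytca = ", x$ytca, ", rtca = ", x$rtca,
      ", other = ", x$other_tca, "\n", sep = "")
  cat("background freq (per 4-mer, both strands): YTCA ",
      signif(x$background_ytca_freq, 4), ", RTCA ",
      signif(x$background_rtca_freq, 4), "\n", sep = "")
  invisible(x)
}

#' Attribute APOBEC-context mutations to A3A-like or A3B-like activity
#'
#' Compares the YTCA:RTCA ratio of qualifying mutations against the genomic
#' background availability of the two contexts. The decision statistic is the
#' background-normalized ratio `(ytca / bg_ytca) / (rtca / bg_rtca)`; the raw
#' `ytca / rtca` ratio is also reported. The label is `A3A-like` when the
#' normalized ratio exceeds `1 + decision_margin`, `A3B-like` when it falls
#' below `1 / (1 + decision_margin)`, and `indeterminate` otherwise or
#' whenever fewer than `min_support` informative (YTCA + RTCA) mutations are
#' available. One zero count with a nonzero other yields an infinite (or
#' zero) ratio and a label is still assigned if support suffices.
#'
#' @param counts A [count_tca_contexts()] result.
#' @param min_support Minimum informative mutations for a call (default 20).
#' @param decision_margin Multiplicative margin around 1 (default 0.10).
#' @return An `attribution_call` list: `ratio_raw`, `ratio_normalized`,
#'   `label`, `n_informative`.
#' @export
attribute_enzyme <- function(counts, min_support = 20L,
                             decision_margin = 0.10) {
  if (min_support < 1L) stop("min_support must be >= 1", call. = FALSE)
  if (decision_margin < 0) {
    stop("decision_margin must be non-negative", call. = FALSE)
  }
  y <- counts$ytca
  r <- counts$rtca
  n_inf <- y + r
  ratio_raw <- if (r > 0) y / r else if (y > 0) Inf else NA_real_
  by <- counts$background_ytca_freq
  br <- counts$background_rtca_freq
  ratio_norm <- if (by > 0 && br > 0) {
    if (r > 0) (y / by) / (r / br) else if (y > 0) Inf else NA_real_
  } else {
    NA_real_
  }
  label <- "indeterminate"
  if (n_inf >= min_support && !is.na(ratio_norm)) {
    if (ratio_norm > 1 + decision_margin) {
      label <- "A3A-like"
    } else if (ratio_norm < 1 / (1 + decision_margin)) {
      label <- "A3B-like"
    }
  }
  structure(
    list(ratio_raw = ratio_raw, ratio_normalized = ratio_norm,
         label = label, n_informative = as.integer(n_inf)),
    class = "attribution_call"
  )
}

#' @export
print.attribution_call <- function(x, ...) {
  cat("enzyme attribution: ", x$label, " (normalized YTCA:RTCA ratio ",
      signif(x$ratio_normalized, 4), ", n = ", x$n_informative, ")\n",
      sep = "")
  invisible(x)
}

#' Per-sample enzyme attribution table
#'
#' Runs [count_tca_contexts()] and [attribute_enzyme()] either per sample or
#' pooled over all samples.
#'
#' @param variants Variant table.
#' @param reference Reference sequences.
#' @param per_sample Attribute each sample separately (default) or pool all
#'   variants into a single call.
#' @inheritParams attribute_enzyme
#' @return Data frame with one row per sample (or a single `pooled` row):
#'   `sample_id`, `ytca`, `rtca`, `ratio_raw`, `ratio_normalized`, `label`,
#'   `n_informative`.
#' @export
attribute_samples <- function(variants, reference, per_sample = TRUE,
                              min_support = 20L, decision_margin = 0.10) {
  variants <- validate_variants(variants)
  groups <- if (per_sample) {
    split(variants, as.character(variants$sample_id))
  } else {
    list(pooled = variants)
  }
  rows <- lapply(names(groups), function(nm) {
    cnt <- count_tca_contexts(groups[[nm]], reference)
    call <- attribute_enzyme(cnt, min_support, decision_margin)
    data.frame(sample_id = nm, ytca = cnt$ytca, rtca = cnt$rtca,
               ratio_raw = call$ratio_raw,
               ratio_normalized = call$ratio_normalized,
               label = call$label, n_informative = call$n_informative,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
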