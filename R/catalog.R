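# Mutation catalog construction: somatic SNVs + reference sequence ->
# pyrimidine-normalized 96-channel trinucleotide counts.

# Accept a synthetic_reference, a named character vector of contig sequences,
# or a Biostrings DNAStringSet; return a named uppercase character vector.
as_reference_seqs <- function(reference) {
  if (inherits(reference, "synthetic_reference")) {
    return(reference$contigs)
  }
  if (inherits(reference, "DNAStringSet")) {
    seqs <- as.character(reference)
    if (is.null(names(seqs))) {
      names(seqs) <- paste0("contig", seq_along(seqs))
    }
    return(toupper(seqs))
  }
  if (is.character(reference)) {
    if (is.null(names(reference))) {
      stop("reference sequences must be named by contig", call. = FALSE)
    }
    return(toupper(reference))
  }
  stop("unsupported reference representation", call. = FALSE)
}

validate_variants <- function(variants) {
  needed <- c("sample_id", "chrom", "pos", "ref", "alt")
  missing <- setdiff(needed, names(variants))
  if (length(missing) > 0) {
    stop("variant table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  variants$pos <- as.integer(variants$pos)
  variants$ref <- toupper(variants$ref)
  variants$alt <- toupper(variants$alt)
  variants
}

#' Extract the sequence window around a position
#'
#' Returns the uppercase window `[pos - flank5, pos + flank3]` (1-based,
#' closed) from the named contig.
#'
#' @param reference Reference sequences: a named character vector, a
#'   `DNAStringSet`, or a [make_reference()] object.
#' @param chrom Contig name.
#' @param pos 1-based position.
#' @param flank5,flank3 Number of bases to include 5' and 3' of `pos`.
#' @return Character string of length `flank5 + 1 + flank3`.
#' @export
#' @examples
#' extract_context(c(chr1 = "ACGTA"), "chr1", 3, 1, 1)  # "CGT"
extract_context <- function(reference, chrom, pos, flank5 = 1L, flank3 = 1L) {
  seqs <- as_reference_seqs(reference)
  if (!chrom %in% names(seqs)) {
    stop("contig not in reference: ", chrom, call. = FALSE)
  }
  s <- seqs[[chrom]]
  start <- pos - flank5
  end <- pos + flank3
  if (start < 1L || end > nchar(s)) {
    stop("context window [", start, ", ", end, "] off contig '", chrom,
         "' of length ", nchar(s), call. = FALSE)
  }
  substr(s, start, end)
}

#' Build a 96-channel mutation catalog
#'
#' Converts a table of somatic single-nucleotide variants into per-sample
#' counts over the 96 pyrimidine-normalized trinucleotide substitution
#' channels. Variants are checked against the reference: records whose REF
#' base does not match the reference, whose context window runs off the
#' contig end, or whose context contains an ambiguous base (N) are skipped
#' and reported, never counted.
#'
#' @param variants Data frame with columns `sample_id`, `chrom`, `pos`
#'   (1-based), `ref`, `alt`.
#' @param reference Reference sequences (see [extract_context()]).
#' @param samples Optional character vector fixing the catalog columns (e.g.
#'   to keep a sample whose variants were all skipped, or an empty sample);
#'   defaults to the samples present in `variants`.
#' @return A `mutation_catalog`: an integer matrix with 96 rows in
#'   [sbs_channels()] order and one column per sample, with a `skip_report`
#'   attribute (data frame of skipped variants and reasons).
#' @export
build_catalog <- function(variants, reference, samples = NULL) {
  seqs <- as_reference_seqs(reference)
  variants <- validate_variants(variants)
  if (is.null(samples)) {
    samples <- unique(as.character(variants$sample_id))
  }
  channels <- sbs_channels()
  counts <- matrix(0L, nrow = 96L, ncol = length(samples),
                   dimnames = list(channels, samples))

  n <- nrow(variants)
  reason <- rep(NA_character_, n)
  channel <- rep(NA_character_, n)

  if (n > 0) {
    bad_contig <- !(variants$chrom %in% names(seqs))
    reason[bad_contig] <- "unknown_contig"
    lens <- rep(NA_integer_, n)
    lens[!bad_contig] <- nchar(seqs)[variants$chrom[!bad_contig]]
    off <- !bad_contig & (variants$pos < 2L | variants$pos > lens - 1L)
    reason[off] <- "context_off_contig"
    not_snv <- !nzchar(variants$ref) | !nzchar(variants$alt) |
      nchar(variants$ref) != 1L | nchar(variants$alt) != 1L |
      !(variants$ref %in% DNA_BASES) | !(variants$alt %in% DNA_BASES) |
      variants$ref == variants$alt
    reason[not_snv & is.na(reason)] <- "not_snv"

    ok <- is.na(reason)
    if (any(ok)) {
      ctx <- substr(seqs[variants$chrom[ok]],
                    variants$pos[ok] - 1L, variants$pos[ok] + 1L)
      center <- substr(ctx, 2L, 2L)
      mism <- center != variants$ref[ok]
      amb <- grepl("[^ACGT]", ctx)
      r <- rep(NA_character_, sum(ok))
      r[amb] <- "ambiguous_context"
      r[mism & is.na(r)] <- "ref_mismatch"
      reason[ok] <- r
      good <- ok
      good[ok] <- is.na(r)
      if (any(good)) {
        channel[good] <- channel_of(variants$ref[good], variants$alt[good],
                                    substr(seqs[variants$chrom[good]],
                                           variants$pos[good] - 1L,
                                           variants$pos[good] + 1L))
        tab <- table(factor(channel[good], levels = channels),
                     factor(as.character(variants$sample_id[good]),
                            levels = samples))
        counts <- counts + matrix(as.integer(tab), nrow = 96L,
                                  dimnames = dimnames(counts))
      }
    }
  }

  skipped <- which(!is.na(reason))
  skip_report <- data.frame(
    sample_id = as.character(variants$sample_id[skipped]),
    chrom = as.character(variants$chrom[skipped]),
    pos = variants$pos[skipped],
    reason = reason[skipped],
    stringsAsFactors = FALSE
  )
  empty <- samples[colSums(counts) == 0L]
  if (length(empty) > 0 && n > 0) {
    warning("all variants skipped for sample(s): ",
            paste(empty, collapse = ", "), call. = FALSE)
  }
  structure(counts, skip_report = skip_report,
            class = c("mutation_catalog", class(counts)))
}

#' @export
print.mutation_catalog <- function(x, ...) {
  cat("96-channel mutation catalog: ", ncol(x), " sample(s), ",
      sum(x), " mutation(s)\n", sep = "")
  skips <- attr(x, "skip_report")
  if (!is.null(skips) && nrow(skips) > 0) {
    cat("skipped variants:", nrow(skips), "\n")
  }
  invisible(x)
}

# matrix with rows forced to the channel order; used when reading catalogs
as_catalog_matrix <- function(m) {
  channels <- sbs_channels()
  if (is.null(rownames(m)) || !setequal(rownames(m), channels)) {
    stop("catalog must have the 96 standard channel row names", call. = FALSE)
  }
  m <- as.matrix(m)[channels, , drop = FALSE]
  storage.mode(m) <- "double"
  m
}
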