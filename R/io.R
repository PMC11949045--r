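# Readers and writers for the plain-text formats the pipeline exchanges:
# FASTA references, VCF v4.2 variants, TSV tables (catalogs, signatures,
# exposures, cohorts, expression) and GMT gene sets.

#' Read a reference FASTA
#'
#' @param path FASTA file.
#' @return Named character vector of uppercase contig sequences.
#' @export
read_reference_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(seqs))
  # drop FASTA description after the first whitespace
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' Write a reference FASTA
#'
#' @param reference Reference sequences (see [extract_context()]).
#' @param path Output file.
#' @export
write_reference_fasta <- function(reference, path) {
  seqs <- as_reference_seqs(reference)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read somatic SNVs from a VCF
#'
#' Parses a VCF v4.2 file, splits multi-allelic records into one row per ALT
#' allele, and keeps single-nucleotide substitutions only; skipped records
#' are reported in the `skip_report` attribute.
#'
#' @param path VCF file (uncompressed or bgzipped).
#' @param sample_id Sample label to assign; defaults to the file name
#'   without extension.
#' @return Variant data frame (`sample_id`, `chrom`, `pos`, `ref`, `alt`).
#' @export
read_variants_vcf <- function(path, sample_id = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package", call. = FALSE)
  }
  if (is.null(sample_id)) {
    sample_id <- sub("\\.vcf(\\.gz)?$", "", basename(path))
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(data.frame(sample_id = character(), chrom = character(),
                      pos = integer(), ref = character(), alt = character(),
                      stringsAsFactors = FALSE))
  }
  alt_list <- strsplit(fix$ALT, ",", fixed = TRUE)
  n_alt <- lengths(alt_list)
  expanded <- data.frame(
    sample_id = sample_id,
    chrom = rep(fix$CHROM, n_alt),
    pos = rep(as.integer(fix$POS), n_alt),
    ref = toupper(rep(fix$REF, n_alt)),
    alt = toupper(unlist(alt_list)),
    stringsAsFactors = FALSE
  )
  snv <- nchar(expanded$ref) == 1L & nchar(expanded$alt) == 1L &
    expanded$ref %in% DNA_BASES & expanded$alt %in% DNA_BASES &
    expanded$ref != expanded$alt
  out <- expanded[snv, , drop = FALSE]
  rownames(out) <- NULL
  skip <- expanded[!snv, , drop = FALSE]
  skip$reason <- rep("not_snv", nrow(skip))
  attr(out, "skip_report") <- skip
  out
}

#' Write variants as minimal VCF v4.2
#'
#' @param variants Variant data frame (single-ALT SNVs, 1-based positions).
#' @param path Output file.
#' @export
write_variants_vcf <- function(variants, path) {
  variants <- validate_variants(variants)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=apobecemt",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\tSAMPLE=%s",
                  variants$chrom, variants$pos, variants$ref, variants$alt,
                  variants$sample_id)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read / write a variant TSV
#'
#' Tab-delimited table with columns `sample_id`, `chrom`, `pos`, `ref`,
#' `alt`.
#'
#' @param path File path.
#' @return `read_variants_tsv()`: variant data frame.
#' @export
read_variants_tsv <- function(path) {
  validate_variants(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_variants_tsv
#' @param variants Variant data frame.
#' @export
write_variants_tsv <- function(variants, path) {
  utils::write.table(validate_variants(variants), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a 96-channel catalog TSV
#'
#' Catalogs are stored with one row per channel (first column `channel`,
#' labels as in [sbs_channels()]) and one column per sample.
#'
#' @param path File path.
#' @return `read_catalog_tsv()`: 96 x samples numeric matrix.
#' @export
read_catalog_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  as_catalog_matrix(m)
}

#' @rdname read_catalog_tsv
#' @param catalog 96 x samples matrix.
#' @export
write_catalog_tsv <- function(catalog, path) {
  m <- as_catalog_matrix(as.matrix(catalog))
  df <- data.frame(channel = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a signature matrix TSV
#'
#' COSMIC-shaped layout: first column holds the 96 channel labels
#' (`"A[C>A]A"`, ...), remaining columns one signature each.
#'
#' @param path File path.
#' @return `read_signature_tsv()`: validated 96 x signatures matrix.
#' @export
read_signature_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  validate_signature_matrix(m)
}

#' @rdname read_signature_tsv
#' @param signatures 96 x signatures matrix, columns summing to 1.
#' @export
write_signature_tsv <- function(signatures, path) {
  m <- validate_signature_matrix(signatures)
  df <- data.frame(channel = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write gene sets in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param path File path.
#' @return `read_gmt()`: named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1L)
  sets
}

#' @rdname read_gmt
#' @param gene_sets Named list of character vectors.
#' @param description Second GMT column (recycled).
#' @export
write_gmt <- function(gene_sets, path, description = "apobecemt") {
  lines <- mapply(function(nm, genes, desc) {
    paste(c(nm, desc, genes), collapse = "\t")
  }, names(gene_sets), gene_sets, rep_len(description, length(gene_sets)))
  writeLines(unname(lines), path)
  invisible(path)
}

#' Read / write an expression matrix TSV
#'
#' Genes x samples, first column gene identifiers.
#'
#' @param path File path.
#' @return `read_expression_tsv()`: numeric matrix, genes x samples.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' @rdname read_expression_tsv
#' @param expr Genes x samples numeric matrix.
#' @export
write_expression_tsv <- function(expr, path) {
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
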