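# Shared fixtures and independent oracles used across the test files.

# naive per-variant catalog: loops over variants one at a time through the
# scalar context/normalization path; independent of the vectorized
# production path in build_catalog()
naive_catalog <- function(variants, reference) {
  seqs <- apobecemt:::as_reference_seqs(reference)
  channels <- sbs_channels()
  samples <- unique(as.character(variants$sample_id))
  counts <- matrix(0L, 96L, length(samples),
                   dimnames = list(channels, samples))
  for (i in seq_len(nrow(variants))) {
    chrom <- as.character(variants$chrom[i])
    pos <- as.integer(variants$pos[i])
    if (!chrom %in% names(seqs)) next
    ctx <- tryCatch(extract_context(seqs, chrom, pos, 1, 1),
                    error = function(e) NULL)
    if (is.null(ctx) || grepl("[^ACGT]", ctx)) next
    if (substr(ctx, 2, 2) != toupper(variants$ref[i])) next
    ch <- channel_of(toupper(variants$ref[i]), toupper(variants$alt[i]), ctx)
    counts[ch, as.character(variants$sample_id[i])] <-
      counts[ch, as.character(variants$sample_id[i])] + 1L
  }
  counts
}

# exhaustive simplex grid search oracle for NNLS relative contributions:
# scans mixture directions w on a step-size grid, fits the overall scale c
# in closed form (c = w'A'b / w'A'A w), and returns the direction minimizing
# ||b - c A w||^2 — the same quantity whose normalized minimizer NNLS
# reports as relative contributions
grid_refit <- function(counts, reference, step = 1e-3) {
  k <- ncol(reference)
  stopifnot(k %in% c(2L, 3L))
  b <- counts / sum(counts)
  steps <- round(1 / step)
  if (k == 2L) {
    w1 <- seq(0, steps) / steps
    grid <- cbind(w1, 1 - w1)
  } else {
    w1 <- rep(seq(0, steps), times = steps + 1) / steps
    w2 <- rep(seq(0, steps), each = steps + 1) / steps
    ok <- w1 + w2 <= 1
    grid <- cbind(w1[ok], w2[ok], 1 - w1[ok] - w2[ok])
  }
  ata <- crossprod(reference)
  atb <- crossprod(reference, b)
  g <- as.vector(grid %*% atb)           # w'A'b
  q <- rowSums((grid %*% ata) * grid)    # w'A'A w
  # residual b'b - g^2 / q is minimized where g^2 / q (g > 0) is maximal
  score <- ifelse(g > 0 & q > 0, g^2 / q, -Inf)
  w <- grid[which.max(score), ]
  names(w) <- colnames(reference)
  w
}

# two toy signatures with disjoint channel support
disjoint_toy_signatures <- function() {
  channels <- sbs_channels()
  a <- rep(0, 96)
  b <- rep(0, 96)
  a[1:8] <- 1 / 8
  b[49:64] <- 1 / 16
  m <- cbind(sigA = a, sigB = b)
  rownames(m) <- channels
  m
}

# flip everything to the opposite strand: reverse-complement each contig and
# mirror variant positions, complementing their alleles
complement_everything <- function(variants, reference) {
  seqs <- apobecemt:::as_reference_seqs(reference)
  rc_seqs <- vapply(seqs, function(s) revcomp(s), character(1))
  lens <- nchar(seqs)
  variants$pos <- lens[variants$chrom] - variants$pos + 1L
  variants$ref <- chartr("ACGT", "TGCA", variants$ref)
  variants$alt <- chartr("ACGT", "TGCA", variants$alt)
  list(variants = variants, reference = rc_seqs)
}

total_variation <- function(p, q) 0.5 * sum(abs(p - q))

shared_test_reference <- local({
  ref <- NULL
  function() {
    if (is.null(ref)) ref <<- make_reference(20000, 0.41, 2, seed = 424242)
    ref
  }
})
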