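# 96-channel trinucleotide substitution conventions shared by the catalog,
# signature and attribution code.

SUBSTITUTION_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
DNA_BASES <- c("A", "C", "G", "T")

#' Standard 96-channel labels
#'
#' Returns the fixed channel order used throughout the package: the six
#' pyrimidine substitution classes (C>A, C>G, C>T, T>A, T>C, T>G), and within
#' each class the 16 flanking-base pairs with the 5' flank varying slowest,
#' both flanks in A, C, G, T order. Labels have the form `"A[C>T]G"`.
#'
#' @return Character vector of length 96.
#' @export
#' @examples
#' head(sbs_channels())
sbs_channels <- function() {
  labs <- character(96)
  i <- 1L
  for (sub in SUBSTITUTION_CLASSES) {
    for (f5 in DNA_BASES) {
      for (f3 in DNA_BASES) {
        labs[i] <- paste0(f5, "[", sub, "]", f3)
        i <- i + 1L
      }
    }
  }
  labs
}

# channel label -> list(class, context) where context is the pyrimidine-
# oriented trinucleotide (e.g. "T[C>T]A" -> class "C>T", context "TCA")
channel_context <- function(channels = sbs_channels()) {
  f5 <- substr(channels, 1L, 1L)
  cls <- substr(channels, 3L, 5L)
  f3 <- substr(channels, 7L, 7L)
  data.frame(
    channel = channels,
    class = cls,
    context = paste0(f5, substr(cls, 1L, 1L), f3),
    stringsAsFactors = FALSE
  )
}

#' Reverse complement of DNA strings
#'
#' Vectorized reverse complement over the strict A/C/G/T alphabet (plus N,
#' which maps to itself).
#'
#' @param x Character vector of DNA strings.
#' @return Character vector of the same length.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

complement_base <- function(x) chartr("ACGTN", "TGCAN", x)

is_pyrimidine <- function(base) base %in% c("C", "T")

#' Pyrimidine-normalize a substitution and its local context
#'
#' Maps a substitution to the strand on which the mutated base is a
#' pyrimidine: when the reference base is a purine (A or G) the substitution
#' and its flanking context are reverse-complemented, so every mutation is
#' expressed as one of C>A, C>G, C>T, T>A, T>C, T>G with a context centered
#' on C or T. This is the convention behind the COSMIC single-base
#' substitution channels.
#'
#' All three arguments are vectorized (recycled to a common length). The
#' context must have odd width with the mutated base at its exact center, so
#' that reverse complementing leaves the mutated base centered; asymmetric
#' windows (such as the YTCA tetranucleotide) are assembled by their callers
#' from symmetric windows.
#'
#' @param ref_base,alt_base Single reference/alternate bases (A/C/G/T).
#' @param context DNA string containing the reference base at its center.
#' @return A data frame with columns `class` (substitution class) and
#'   `context` (normalized context string).
#' @export
#' @examples
#' pyrimidine_normalize("G", "A", "TGA")  # minus-strand C>T at TCA
pyrimidine_normalize <- function(ref_base, alt_base, context) {
  n <- max(length(ref_base), length(alt_base), length(context))
  ref_base <- rep_len(toupper(ref_base), n)
  alt_base <- rep_len(toupper(alt_base), n)
  context <- rep_len(toupper(context), n)
  if (any(ref_base == alt_base)) {
    stop("ref_base and alt_base must differ", call. = FALSE)
  }
  if (!all(ref_base %in% DNA_BASES) || !all(alt_base %in% DNA_BASES)) {
    stop("ref_base and alt_base must be one of A, C, G, T", call. = FALSE)
  }
  width <- nchar(context)
  if (any(width %% 2L == 0L)) {
    stop("context must have odd width with the mutated base at its center",
         call. = FALSE)
  }
  center <- (width + 1L) %/% 2L
  center_base <- substr(context, center, center)
  if (any(center_base != ref_base)) {
    stop("context center does not match ref_base", call. = FALSE)
  }
  flip <- ref_base %in% c("A", "G")
  out_ref <- ref_base
  out_alt <- alt_base
  out_ctx <- context
  if (any(flip)) {
    out_ref[flip] <- complement_base(ref_base[flip])
    out_alt[flip] <- complement_base(alt_base[flip])
    out_ctx[flip] <- revcomp(context[flip])
  }
  data.frame(
    class = paste0(out_ref, ">", out_alt),
    context = out_ctx,
    stringsAsFactors = FALSE
  )
}

#' Map substitutions to 96-channel labels
#'
#' Combines [pyrimidine_normalize()] on trinucleotide contexts with the
#' standard channel layout of [sbs_channels()].
#'
#' @param ref_base,alt_base,context As in [pyrimidine_normalize()]; `context`
#'   must be the 3-base window centered on the mutated base.
#' @return Character vector of channel labels, e.g. `"T[C>T]A"`.
#' @export
channel_of <- function(ref_base, alt_base, context) {
  if (any(nchar(context) != 3L)) {
    stop("channel_of() needs trinucleotide contexts", call. = FALSE)
  }
  norm <- pyrimidine_normalize(ref_base, alt_base, context)
  paste0(substr(norm$context, 1L, 1L), "[", norm$class, "]",
         substr(norm$context, 3L, 3L))
}
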