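# A small curated bundle of reference signature shapes used as the default
# refitting basis and by the simulators. These are synthetic stand-ins: they
# reproduce the qualitative channel structure of the named COSMIC signatures
# (APOBEC C>T and C>G at TpC for SBS2/SBS13, CpG C>T for the clock-like
# SBS1, a flat background for SBS5, C>A for the ROS-like SBS18) but are
# constructed analytically here, not copied from the COSMIC tables. Use
# read_signature_tsv() to refit against a user-supplied reference set.

# deterministic peaked distribution over the 96 channels: `peaks` is a named
# vector of channel weights; `floor_mass` spreads uniform mass everywhere so
# every channel stays attainable
peaked_signature <- function(peaks, floor_mass = 0.05) {
  channels <- sbs_channels()
  p <- rep(floor_mass / 96, 96)
  names(p) <- channels
  bad <- setdiff(names(peaks), channels)
  if (length(bad) > 0) stop("unknown channel(s): ", paste(bad, collapse = ", "))
  p[names(peaks)] <- p[names(peaks)] + (1 - floor_mass) * peaks / sum(peaks)
  p
}

#' Synthetic reference signature bundle
#'
#' A 96 x 5 probability matrix of synthetic signature shapes named after the
#' processes they emulate: `SBS2` (APOBEC3 C>T at TpC), `SBS13` (APOBEC3 C>G
#' at TpC), `SBS1` (deamination of 5-methylcytosine, C>T at CpG), `SBS5`
#' (flat clock-like background), `SBS18` (C>A, oxidative-damage-like). The
#' shapes are analytic stand-ins with the named signatures' qualitative
#' channel structure and low pairwise cosine similarity, suitable as a
#' refitting basis and as simulation ground truth; they are not the COSMIC
#' estimates.
#'
#' @return Numeric matrix, 96 channels x 5 signatures, columns summing to 1.
#' @export
#' @examples
#' ref <- reference_signatures()
#' colSums(ref)
reference_signatures <- function() {
  tpc_3p <- c(A = 0.35, C = 0.20, G = 0.10, T = 0.35)
  sbs2_peaks <- stats::setNames(tpc_3p, paste0("T[C>T]", names(tpc_3p)))
  sbs13_peaks <- stats::setNames(tpc_3p, paste0("T[C>G]", names(tpc_3p)))
  cpg <- c(A = 0.30, C = 0.25, G = 0.20, T = 0.25)
  sbs1_peaks <- stats::setNames(cpg, paste0(names(cpg), "[C>T]G"))
  # SBS18-like: C>A with mild 5'/3' structure
  caa <- expand.grid(f5 = DNA_BASES, f3 = DNA_BASES)
  w18 <- ifelse(caa$f3 == "A", 2, 1) * ifelse(caa$f5 %in% c("G", "T"), 1.5, 1)
  sbs18_peaks <- stats::setNames(w18, paste0(caa$f5, "[C>A]", caa$f3))
  # SBS5-like: near-flat with a mild tilt toward T>C
  channels <- sbs_channels()
  sbs5 <- rep(1, 96)
  names(sbs5) <- channels
  sbs5[grepl("T>C", channels, fixed = TRUE)] <- 2
  sbs5 <- sbs5 / sum(sbs5)

  m <- cbind(
    SBS2 = peaked_signature(sbs2_peaks),
    SBS13 = peaked_signature(sbs13_peaks),
    SBS1 = peaked_signature(sbs1_peaks, floor_mass = 0.10),
    SBS5 = sbs5,
    SBS18 = peaked_signature(sbs18_peaks, floor_mass = 0.15)
  )
  rownames(m) <- channels
  m
}
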