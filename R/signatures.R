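# Signature activity estimation: NNLS refitting against a fixed reference
# set, de novo extraction by KL-NMF with multiplicative updates, and
# cosine-similarity matching of extracted signatures to references.

validate_signature_matrix <- function(reference, tol = 1e-6) {
  m <- as.matrix(reference)
  if (nrow(m) != 96L) {
    stop("signature matrix must have 96 channel rows", call. = FALSE)
  }
  if (ncol(m) < 1L) {
    stop("signature matrix must contain at least one signature", call. = FALSE)
  }
  m <- as_catalog_matrix(m)
  if (any(m < 0)) {
    stop("signature probabilities must be non-negative", call. = FALSE)
  }
  sums <- colSums(m)
  if (any(abs(sums - 1) > tol)) {
    stop("signature columns must sum to 1 (tolerance ", tol, ")",
         call. = FALSE)
  }
  m
}

#' Cosine similarity between spectra
#'
#' @param a,b Numeric vectors of equal length; neither may be all zero.
#' @return `dot(a, b) / (|a| |b|)`, in `[0, 1]` for non-negative inputs.
#' @export
cosine_similarity <- function(a, b) {
  if (length(a) != length(b)) {
    stop("vectors must have equal length", call. = FALSE)
  }
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    stop("cosine similarity undefined for a zero vector", call. = FALSE)
  }
  sum(a * b) / (na * nb)
}

#' Refit catalogs to a fixed reference signature set
#'
#' Per sample, estimates non-negative signature activities minimizing the
#' squared reconstruction error of the 96-channel catalog (classic NNLS
#' refitting). Relative activities are the absolute activities normalized to
#' sum 1.
#'
#' @param catalog A 96 x samples catalog matrix ([build_catalog()]).
#' @param reference A 96 x signatures probability matrix, columns summing
#'   to 1, rows in [sbs_channels()] order.
#' @return An `exposure_result` list:
#'   \describe{
#'     \item{absolute}{signatures x samples matrix of activities (mutation
#'       units).}
#'     \item{relative}{signatures x samples matrix summing to 1 per sample;
#'       all-`NA` column for an all-zero sample.}
#'     \item{reconstruction_residual}{per-sample relative L2 error
#'       `|catalog - reconstruction| / |catalog|`.}
#'     \item{cosine_to_data}{per-sample cosine between catalog and
#'       reconstruction.}
#'   }
#' @export
fit_exposures <- function(catalog, reference) {
  ref <- validate_signature_matrix(reference)
  cat_m <- as_catalog_matrix(as.matrix(catalog))
  if (any(cat_m < 0)) {
    stop("catalog counts must be non-negative", call. = FALSE)
  }
  k <- ncol(ref)
  s <- ncol(cat_m)
  absolute <- matrix(0, nrow = k, ncol = s,
                     dimnames = list(colnames(ref), colnames(cat_m)))
  relative <- absolute
  resid <- numeric(s)
  cosine <- numeric(s)
  names(resid) <- names(cosine) <- colnames(cat_m)
  for (j in seq_len(s)) {
    b <- cat_m[, j]
    tot <- sum(b)
    if (tot == 0) {
      relative[, j] <- NA_real_
      resid[j] <- NA_real_
      cosine[j] <- NA_real_
      next
    }
    x <- pracma::lsqnonneg(ref, b)$x
    absolute[, j] <- x
    recon <- as.vector(ref %*% x)
    resid[j] <- sqrt(sum((b - recon)^2)) / sqrt(sum(b^2))
    cosine[j] <- cosine_similarity(b, recon)
    xs <- sum(x)
    relative[, j] <- if (xs > 0) x / xs else NA_real_
  }
  structure(
    list(absolute = absolute, relative = relative,
         reconstruction_residual = resid, cosine_to_data = cosine),
    class = "exposure_result"
  )
}

#' @export
print.exposure_result <- function(x, ...) {
  cat("signature exposures: ", nrow(x$absolute), " signature(s) x ",
      ncol(x$absolute), " sample(s)\n", sep = "")
  cat("mean cosine to data: ",
      round(mean(x$cosine_to_data, na.rm = TRUE), 4), "\n", sep = "")
  invisible(x)
}

#' Summed relative contribution of a signature subset
#'
#' The per-sample fraction of total activity attributed to the named
#' signatures. `apobec_fraction()` is the call with subset
#' `c("SBS2", "SBS13")`, the fraction of mutational burden attributed to
#' APOBEC3 activity.
#'
#' @param exposures An [fit_exposures()] result.
#' @param signature_subset Character vector of signature names.
#' @return Named numeric vector, one fraction in `[0, 1]` per sample (`NA`
#'   for all-zero samples).
#' @export
relative_contribution <- function(exposures, signature_subset) {
  rel <- exposures$relative
  unknown <- setdiff(signature_subset, rownames(rel))
  if (length(unknown) > 0) {
    stop("unknown signature name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  colSums(rel[signature_subset, , drop = FALSE])
}

#' @rdname relative_contribution
#' @export
apobec_fraction <- function(exposures) {
  relative_contribution(exposures, c("SBS2", "SBS13"))
}

generalized_kl <- function(v, wh) {
  pos <- v > 0
  sum(v[pos] * log(v[pos] / wh[pos]) - v[pos]) + sum(wh)
}

#' De novo signature extraction by KL-NMF
#'
#' Factorizes a 96 x samples catalog into `rank` signatures and their
#' exposures by non-negative matrix factorization under the generalized
#' Kullback-Leibler divergence, using multiplicative updates. Multiple
#' random restarts are run and the factorization with the lowest final
#' objective is kept. Signature columns are renormalized to sum 1 with the
#' scale folded into the exposures, so exposures stay in mutation units.
#'
#' @param catalogs 96 x samples catalog matrix.
#' @param rank Number of signatures to extract (1 to `min(96, n_samples)`).
#' @param n_restarts Random restarts (default 20).
#' @param max_iter Maximum multiplicative-update iterations per restart.
#' @param tol Relative objective change declaring convergence.
#' @param seed Integer seed; restart r uses seed `seed + r - 1`.
#' @return An `nmf_result` list with `signatures` (96 x rank, columns sum
#'   to 1), `exposures` (rank x samples), `objective_trace` (per-iteration
#'   generalized KL of the best restart), `converged`, `restarts_used`,
#'   `best_seed`.
#' @export
nmf_extract <- function(catalogs, rank, n_restarts = 20L, max_iter = 2000L,
                        tol = 1e-6, seed = 1L) {
  v <- as_catalog_matrix(as.matrix(catalogs))
  if (any(v < 0)) stop("catalog counts must be non-negative", call. = FALSE)
  n <- ncol(v)
  if (rank < 1L || rank > min(96L, n)) {
    stop("rank must lie in [1, min(96, n_samples)]", call. = FALSE)
  }
  eps <- 1e-12
  best <- NULL
  for (r in seq_len(n_restarts)) {
    restart_seed <- seed + r - 1L
    set.seed(restart_seed)
    scale0 <- sqrt(mean(v) / rank + eps)
    w <- matrix(stats::runif(96L * rank, 0.5, 1.5) * scale0, 96L, rank)
    h <- matrix(stats::runif(rank * n, 0.5, 1.5) * scale0, rank, n)
    trace <- numeric(0)
    obj_prev <- Inf
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      wh <- pmax(w %*% h, eps)
      w <- w * ((v / wh) %*% t(h))
      w <- sweep(w, 2L, pmax(rowSums(h), eps), "/")
      wh <- pmax(w %*% h, eps)
      h <- h * (t(w) %*% (v / wh))
      h <- sweep(h, 1L, pmax(colSums(w), eps), "/")
      obj <- generalized_kl(v, pmax(w %*% h, eps))
      trace <- c(trace, obj)
      if (is.finite(obj_prev) &&
          abs(obj_prev - obj) <= tol * max(abs(obj_prev), eps)) {
        converged <- TRUE
        break
      }
      obj_prev <- obj
    }
    final <- trace[length(trace)]
    if (is.null(best) || final < best$objective) {
      best <- list(w = w, h = h, trace = trace, objective = final,
                   converged = converged, seed = restart_seed)
    }
  }
  scale <- colSums(best$w)
  w <- sweep(best$w, 2L, pmax(scale, eps), "/")
  h <- best$h * scale
  sig_names <- paste0("DN", seq_len(rank))
  dimnames(w) <- list(rownames(v), sig_names)
  dimnames(h) <- list(sig_names, colnames(v))
  if (!best$converged) {
    warning("NMF did not reach the convergence tolerance within max_iter",
            call. = FALSE)
  }
  structure(
    list(rank = rank, signatures = w, exposures = h,
         objective_trace = best$trace, converged = best$converged,
         restarts_used = n_restarts, best_seed = best$seed),
    class = "nmf_result"
  )
}

#' @export
print.nmf_result <- function(x, ...) {
  cat("KL-NMF extraction: rank ", x$rank, ", ", ncol(x$exposures),
      " sample(s)\n", sep = "")
  cat("final objective: ",
      format(x$objective_trace[length(x$objective_trace)]),
      if (x$converged) " (converged)" else " (max_iter reached)", "\n",
      sep = "")
  invisible(x)
}

# all injective assignments of r items into k slots, as an r x n matrix;
# only used for small problems
assignment_candidates <- function(k, r) {
  combos <- utils::combn(k, r)
  perms <- pracma::perms(seq_len(r))
  out <- matrix(0L, nrow = r,
                ncol = ncol(combos) * nrow(perms))
  idx <- 1L
  for (j in seq_len(ncol(combos))) {
    for (p in seq_len(nrow(perms))) {
      out[, idx] <- combos[perms[p, ], j]
      idx <- idx + 1L
    }
  }
  out
}

#' Match de novo signatures to a reference set
#'
#' Assigns each extracted signature to a distinct reference signature so the
#' total cosine similarity is maximal (exhaustive assignment for small
#' problems, greedy otherwise), and flags pairs whose cosine falls below a
#' reporting floor as unassigned.
#'
#' @param denovo,reference 96 x k probability matrices sharing the standard
#'   channel order.
#' @param min_cosine Reporting floor below which a pair is flagged.
#' @return Data frame with columns `denovo`, `reference`, `cosine`,
#'   `assigned`.
#' @export
match_signatures <- function(denovo, reference, min_cosine = 0.75) {
  dn <- validate_signature_matrix(denovo)
  ref <- validate_signature_matrix(reference)
  r <- ncol(dn)
  k <- ncol(ref)
  if (r > k) {
    stop("more de novo signatures than references; cannot assign one-to-one",
         call. = FALSE)
  }
  cm <- matrix(0, r, k)
  for (i in seq_len(r)) {
    for (j in seq_len(k)) cm[i, j] <- cosine_similarity(dn[, i], ref[, j])
  }
  n_cand <- choose(k, r) * factorial(r)
  if (n_cand <= 2e5) {
    cand <- assignment_candidates(k, r)
    scores <- colSums(matrix(cm[cbind(rep(seq_len(r), ncol(cand)),
                                      as.vector(cand))],
                             nrow = r))
    pick <- cand[, which.max(scores)]
  } else {
    # greedy fallback: repeatedly take the best remaining pair
    pick <- integer(r)
    cm_work <- cm
    for (step in seq_len(r)) {
      ij <- arrayInd(which.max(cm_work), dim(cm_work))
      pick[ij[1]] <- ij[2]
      cm_work[ij[1], ] <- -Inf
      cm_work[, ij[2]] <- -Inf
    }
  }
  cos <- cm[cbind(seq_len(r), pick)]
  data.frame(
    denovo = colnames(dn),
    reference = colnames(ref)[pick],
    cosine = cos,
    assigned = cos >= min_cosine,
    stringsAsFactors = FALSE
  )
}

#' Backward elimination of redundant reference signatures
#'
#' Optional sparsification of a refit: starting from the full reference set,
#' repeatedly drops the signature whose removal degrades the per-sample
#' cosine between catalog and reconstruction the least, while the worst
#' degradation stays below `max_delta_cosine`. Full-reference refitting is
#' prone to distributing activity over many similar signatures; this trims
#' signatures the data cannot support.
#'
#' @param catalog 96 x samples catalog matrix.
#' @param reference 96 x signatures probability matrix.
#' @param max_delta_cosine Largest tolerated drop in any sample's
#'   `cosine_to_data` when removing one signature (default 0.01).
#' @param keep Signature names never dropped (default none).
#' @return An `exposure_result` from the reduced set, with attribute
#'   `retained` (character vector of kept signature names).
#' @export
prune_reference_refit <- function(catalog, reference,
                                  max_delta_cosine = 0.01, keep = character()) {
  ref <- validate_signature_matrix(reference)
  active <- colnames(ref)
  fit <- fit_exposures(catalog, ref[, active, drop = FALSE])
  repeat {
    droppable <- setdiff(active, keep)
    if (length(droppable) == 0 || length(active) <= 1L) break
    base_cos <- fit$cosine_to_data
    best_name <- NULL
    best_fit <- NULL
    best_delta <- Inf
    for (nm in droppable) {
      trial <- setdiff(active, nm)
      f2 <- fit_exposures(catalog, ref[, trial, drop = FALSE])
      delta <- max(base_cos - f2$cosine_to_data, na.rm = TRUE)
      if (delta < best_delta) {
        best_delta <- delta
        best_name <- nm
        best_fit <- f2
      }
    }
    if (best_delta < max_delta_cosine) {
      active <- setdiff(active, best_name)
      fit <- best_fit
    } else {
      break
    }
  }
  attr(fit, "retained") <- active
  fit
}
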