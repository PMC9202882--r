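# Spike-triggered covariance: nonlinear figure-ground subspaces as
# eigenvectors of the spike-weighted label covariance minus the baseline
# label covariance, with a randomized eigenvalue-difference significance
# rule.

#' Normalized per-stimulus spike weights
#'
#' Per-stimulus spike totals divided by their mean, so the weights average
#' to one. Under the null of equal responsiveness all weights are 1 and
#' the spike-weighted covariance equals the baseline covariance exactly.
#'
#' @param spikes An \code{fg_spikes} table.
#' @param ids Optional stimulus ids fixing the order.
#' @return Named numeric weight vector with mean 1.
#' @export
normalize_spikes <- function(spikes, ids = NULL) {
  s <- spike_totals(spikes, ids)
  if (sum(s) <= 0)
    stop("normalize_spikes: all spike counts are zero", call. = FALSE)
  s / mean(s)
}

#' Spike-triggered covariance of figure-ground labels
#'
#' Computes the symmetric difference between the spike-weighted and
#' baseline covariance of the STA-centered labels,
#' \deqn{C_{spike} - C_{base} = \tfrac{1}{N-1}\sum_i w_i (L_i - K)(L_i - K)^T
#'   - \tfrac{1}{N-1}\sum_i (L_i - K)(L_i - K)^T,}
#' with \eqn{w_i} the normalized spike weights and \eqn{K} the STA kernel
#' (subtracted because the spike-triggered stimulus distribution is biased
#' relative to the ensemble), and eigendecomposes it. All G^2 eigenpairs
#' are returned, ranked \code{1+, 2+, ...} from the largest positive and
#' \code{1-, 2-, ...} from the smallest negative eigenvalue.
#'
#' The weighted form (weights outside the outer product) is the default;
#' \code{literal = TRUE} instead multiplies each label by its weight inside
#' the outer product, which scales the quadratic form with the squared
#' spike count and breaks the null identity \eqn{C_{spike} = C_{base}}
#' under uniform weights -- it is provided for comparison only.
#'
#' @param labels An \code{fg_stimset}.
#' @param weights Output of \code{\link{normalize_spikes}} (or an
#'   \code{fg_spikes} table, normalized internally).
#' @param sta The \code{rffg} STA of the same (labels, spikes), or a plain
#'   matrix.
#' @param literal Use the literal weights-inside reading (default
#'   \code{FALSE}).
#' @return Object of class \code{"rffg_stc"}: \code{eigenvalues}
#'   (decreasing), \code{eigenvectors} (G^2 x G^2, columns, unit norm),
#'   \code{rank_labels}, \code{grid_size}, \code{matrix} (the symmetric
#'   difference), \code{significant} (filled by
#'   \code{\link{significant_stcs}}).
#' @export
rffg_stc <- function(labels, weights, sta, literal = FALSE) {
  stopifnot(inherits(labels, "fg_stimset"))
  if (inherits(weights, "fg_spikes"))
    weights <- normalize_spikes(weights, names(labels$labels))
  K <- if (inherits(sta, "rffg")) as.vector(sta$grid) else as.vector(sta)
  Lm <- label_matrix(labels)
  C <- stc_matrix(Lm, as.numeric(weights[names(labels$labels)]), K, literal)
  eg <- eigen(C, symmetric = TRUE)
  G <- labels$grid_size
  structure(list(eigenvalues = eg$values, eigenvectors = eg$vectors,
                 rank_labels = stc_rank_labels(eg$values),
                 grid_size = G, matrix = C, literal = literal,
                 significant = rep(NA, length(eg$values)),
                 null_stats = NULL),
            class = "rffg_stc")
}

# The symmetric difference covariance from stacked labels (N x G^2),
# weights w (mean 1) and centering vector K.
stc_matrix <- function(Lm, w, K, literal = FALSE) {
  N <- nrow(Lm)
  if (literal) {
    Dw <- Lm * w - matrix(K, N, length(K), byrow = TRUE)
    D0 <- Lm - matrix(K, N, length(K), byrow = TRUE)
    C <- (crossprod(Dw) - crossprod(D0)) / (N - 1)
  } else {
    D <- Lm - matrix(K, N, length(K), byrow = TRUE)
    C <- (crossprod(D * sqrt(w)) - crossprod(D)) / (N - 1)
  }
  (C + t(C)) / 2
}

# Rank labels "1+", "2+", ... from the top, "1-", "2-", ... from the
# bottom of the eigenvalue spectrum (values sorted decreasing).
stc_rank_labels <- function(values) {
  n <- length(values)
  half <- ceiling(n / 2)
  lab <- character(n)
  lab[seq_len(half)] <- paste0(seq_len(half), "+")
  lab[n + 1 - seq_len(n - half)] <- paste0(seq_len(n - half), "-")
  lab
}

#' Extract an STC eigenvector as a kernel
#'
#' @param stc An \code{rffg_stc}.
#' @param rank Rank label, e.g. \code{"1+"} or \code{"2-"}.
#' @return An \code{\link{rffg}} with estimator \code{"STC"} and
#'   annotations \code{eigenvalue}, \code{rank}, \code{significant}.
#' @export
stc_kernel <- function(stc, rank) {
  i <- match(rank, stc$rank_labels)
  if (is.na(i)) stop("stc_kernel: unknown rank label ", rank, call. = FALSE)
  rffg(matrix(stc$eigenvectors[, i], stc$grid_size, stc$grid_size),
       estimator = "STC", eigenvalue = stc$eigenvalues[i], rank = rank,
       significant = stc$significant[i])
}

#' @export
print.rffg_stc <- function(x, ...) {
  nsig <- sum(x$significant, na.rm = TRUE)
  cat(sprintf("<rffg_stc> %d eigenpairs on a %dx%d grid; eigenvalues [%.3g, %.3g]%s\n",
              length(x$eigenvalues), x$grid_size, x$grid_size,
              min(x$eigenvalues), max(x$eigenvalues),
              if (all(is.na(x$significant))) " (significance not assessed)"
              else sprintf("; %d significant", nsig)))
  invisible(x)
}

#' Select significant STC kernels by the randomized eigenvalue-difference rule
#'
#' Builds null eigenvalue spectra by shuffling the stimulus-to-spike-count
#' assignment \code{n_rand} times and recomputing the STC spectrum (the
#' STA is recomputed per shuffle as well). The differences between
#' consecutive eigenvalues along the rank order are summarized per rank by
#' their null mean and SD. An observed eigenvector is significant when
#' (1) its rank-local eigenvalue difference exceeds the null mean + 1 SD at
#' that rank (gap toward the spectrum interior, from the positive or the
#' negative end), and (2) its neighbor nearer the spectrum extreme is also
#' significant (chaining; the extreme ranks 1+/1- need only criterion 1).
#'
#' @param stc An \code{\link{rffg_stc}}.
#' @param labels,spikes The inputs the STC was computed from.
#' @param n_rand Number of randomizations (default 1000).
#' @param seed Integer seed.
#' @return The \code{rffg_stc} with \code{significant} (logical per
#'   eigenvector) and \code{null_stats} (per-rank mean/SD of null
#'   differences from each end) filled.
#' @export
significant_stcs <- function(stc, labels, spikes, n_rand = 1000, seed = 1L) {
  stopifnot(inherits(stc, "rffg_stc"), n_rand >= 1)
  s <- spike_totals(spikes, names(labels$labels))
  Lm <- label_matrix(labels)
  n <- length(stc$eigenvalues)
  set.seed(seed)
  # Null spectra under shuffled assignment; only eigenvalues are needed.
  diffs <- matrix(NA_real_, n_rand, n - 1)
  for (r in seq_len(n_rand)) {
    sp <- sample(s)
    w <- sp / mean(sp)
    K <- as.vector(crossprod(Lm, sp)) / sum(sp) - colMeans(Lm)
    ev <- eigen(stc_matrix(Lm, w, K, stc$literal), symmetric = TRUE,
                only.values = TRUE)$values
    diffs[r, ] <- -diff(ev)   # positive gaps, rank i vs i+1
  }
  mu <- colMeans(diffs); sdv <- apply(diffs, 2, stats::sd)
  obs_gap <- -diff(stc$eigenvalues)
  # Criterion 1, evaluated from each end: positive ranks look at the gap
  # below them (i vs i+1); negative ranks at the gap above (i-1 vs i).
  half <- ceiling(n / 2)
  crit1 <- logical(n)
  for (i in seq_len(n)) {
    g <- if (i <= half) i else i - 1L     # gap index toward the interior
    crit1[i] <- obs_gap[g] > mu[g] + sdv[g]
  }
  # Criterion 2: chain from the extremes.
  sig <- logical(n)
  for (i in seq_len(half)) {            # from the top (positive end)
    if (!crit1[i] || stc$eigenvalues[i] <= 0) break
    sig[i] <- TRUE
  }
  for (i in seq(n, half + 1)) {         # from the bottom (negative end)
    if (!crit1[i] || stc$eigenvalues[i] >= 0) break
    sig[i] <- TRUE
  }
  stc$significant <- sig
  stc$null_stats <- list(mean = mu, sd = sdv)
  stc
}
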