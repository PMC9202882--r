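# Stimulus-design validation: for model cells with known kernels, compare
# the kernels recovered from patch-style (non-white) label ensembles with
# those recovered from the exhaustive single-cell dot ensemble (white).

#' Validate a label ensemble against the white dot ensemble
#'
#' For each truth kernel, simulates a noiseless rectified-linear cell and
#' estimates its STA twice: from the supplied label set and from the
#' exhaustive +/-1 dot set. On the dot set the pair of opposite-sign dots
#' at cell i contributes \code{max(k_i, 0) - max(-k_i, 0) = k_i}, so the
#' dot-derived STA is exactly proportional to the truth kernel
#' (cosine 1 analytically). The label-derived STA degrades with the label
#' ensemble's spatial autocorrelation; the comparison quantifies how much.
#' Similarities are also reported restricted to a central disc of radius
#' \code{half_crf_sd} cells (half a typical CRF extent), where the
#' patch-derived estimate is most trustworthy.
#'
#' @param kernels List of G x G truth kernels (unit norm recommended), or
#'   a single matrix.
#' @param labels An \code{fg_stimset} of patch-style labels.
#' @param half_crf_sd Radius (cells) of the central subregion (default 3).
#' @param gain Gain of the simulated cells (default 1000; large so that
#'  rounding expected counts to integers is negligible; scales counts but
#'   not the estimate).
#' @param seed Integer seed (simulations are noiseless; the seed fixes any
#'   downstream use).
#' @return Data frame of class \code{"fg_validation"}: one row per kernel
#'   with \code{cos_truth_dot}, \code{cos_label_dot},
#'   \code{cos_label_dot_center}, \code{ok} (FALSE for degenerate zero
#'   estimates, with NA similarities).
#' @export
run_validation <- function(kernels, labels, half_crf_sd = 3, gain = 1000,
                           seed = 1L) {
  stopifnot(inherits(labels, "fg_stimset"))
  if (is.matrix(kernels)) kernels <- list(kernels)
  G <- labels$grid_size
  dots <- gen_dot_stimuli(G)
  ctr <- (G - 1) / 2
  rr <- matrix(rep(seq_len(G) - 1, times = G), G, G)
  cc <- matrix(rep(seq_len(G) - 1, each = G), G, G)
  central <- ((rr - ctr)^2 + (cc - ctr)^2) <= half_crf_sd^2
  one <- function(k) {
    k <- as.matrix(k)
    if (!all(dim(k) == c(G, G)))
      stop("run_validation: kernel size does not match labels", call. = FALSE)
    neuron <- virtual_neuron("rectified_linear", kernel = k, gain = gain)
    est <- function(set) {
      sp <- simulate_responses(neuron, set, n_trials = 1, seed = seed)
      if (sum(sp$stim_count) == 0) return(NULL)
      rffg_sta(set, sp, n_perm = 0)$grid
    }
    sd_ <- est(dots); sl <- est(labels)
    if (is.null(sd_) || is.null(sl) || sum(sd_^2) == 0 || sum(sl^2) == 0 ||
        sum(k^2) == 0)
      return(data.frame(cos_truth_dot = NA_real_, cos_label_dot = NA_real_,
                        cos_label_dot_center = NA_real_, ok = FALSE))
    ctr_ok <- sum(sd_[central]^2) > 0 && sum(sl[central]^2) > 0
    data.frame(
      cos_truth_dot = cosine_similarity(k, sd_),
      cos_label_dot = cosine_similarity(sl, sd_),
      cos_label_dot_center = if (ctr_ok)
        sum(sl[central] * sd_[central]) /
          sqrt(sum(sl[central]^2) * sum(sd_[central]^2)) else NA_real_,
      ok = TRUE)
  }
  out <- do.call(rbind, lapply(kernels, one))
  rownames(out) <- NULL
  class(out) <- c("fg_validation", "data.frame")
  out
}
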