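# Adaptive-filter (exponentially weighted recursive least squares)
# estimation of the linear figure-ground kernel. The filter sequentially
# takes (FG label, spike rate) pairs; the simulated response is the inner
# product of the current kernel with the label, and each update moves the
# kernel to reduce the prediction error under a forgetting factor.

#' Adaptive-filter configuration
#'
#' @param delta_inv Initial inverse-correlation scale: the
#'   inverse-correlation matrix starts at \code{(1/delta_inv) * I}, so with
#'   \code{beta = 1} the final kernel equals the ridge least-squares
#'   solution with regularization \code{delta_inv}. Default 1e-5.
#' @param mu Leakage factor (0 disables; default 0).
#' @param beta Forgetting factor in (0, 1]; default 0.99.
#' @param Q Interval (in updates) of the periodic numerical guard that
#'   re-symmetrizes the inverse-correlation matrix; default 100.
#' @param n_pairs_target Minimum number of input pairs; the pair list is
#'   duplicated whole until this is reached. Default 4200
#'   (210 stimuli x 2 contrasts x 10 trials).
#' @param window_s Stimulus-window length in seconds used to convert
#'   counts to rates in Hz (default 0.16, i.e. 40-200 ms).
#' @param seed Seed for the presentation-order shuffle.
#' @return Object of class \code{"af_config"}.
#' @export
af_config <- function(delta_inv = 1e-5, mu = 0, beta = 0.99, Q = 100,
                      n_pairs_target = 4200, window_s = 0.16, seed = 1L) {
  stopifnot(delta_inv > 0, beta > 0, beta <= 1, mu >= 0, mu < 1, Q >= 1)
  structure(list(delta_inv = delta_inv, mu = mu, beta = beta, Q = Q,
                 n_pairs_target = n_pairs_target, window_s = window_s,
                 seed = seed),
            class = "af_config")
}

#' Build the ordered (label, rate) pair sequence for the adaptive filter
#'
#' One pair per (stimulus, trial) row of the spike table, with the rate in
#' Hz (\code{stim_count / window_s}). If fewer than
#' \code{config$n_pairs_target} pairs exist, the whole list is duplicated
#' until the target is met. The presentation order is randomized under the
#' config seed subject to no two consecutive pairs sharing a stimulus.
#'
#' @param labels An \code{fg_stimset}.
#' @param spikes Matching \code{fg_spikes} table.
#' @param config An \code{\link{af_config}}.
#' @return List of class \code{"af_pairs"}: \code{X} (n_pairs x G^2 label
#'   matrix), \code{y} (rates, Hz), \code{ids}, \code{grid_size}.
#' @export
prepare_pairs <- function(labels, spikes, config = af_config()) {
  stopifnot(inherits(labels, "fg_stimset"))
  miss <- setdiff(spikes$stimulus_id, names(labels$labels))
  if (length(miss))
    stop("prepare_pairs: spikes reference unknown stimuli: ",
         paste(utils::head(miss, 3), collapse = ", "), call. = FALSE)
  ids <- spikes$stimulus_id
  y <- spikes$stim_count / config$window_s
  reps <- max(1L, ceiling(config$n_pairs_target / length(ids)))
  ids <- rep(ids, reps)
  y <- rep(y, reps)
  ord <- no_repeat_order(ids, seed = config$seed)
  ids <- ids[ord]; y <- y[ord]
  Lm <- label_matrix(labels)
  list_out <- list(X = Lm[match(ids, names(labels$labels)), , drop = FALSE],
                   y = y, ids = ids, grid_size = labels$grid_size)
  class(list_out) <- "af_pairs"
  list_out
}

# Random order with no two consecutive equal ids; error when impossible.
no_repeat_order <- function(ids, seed = 1L, max_tries = 200) {
  n <- length(ids)
  if (n > 1 && length(unique(ids)) == 1)
    stop("prepare_pairs: cannot order pairs without repeats (single stimulus)",
         call. = FALSE)
  set.seed(seed)
  for (try in seq_len(max_tries)) {
    ord <- sample.int(n)
    v <- ids[ord]
    bad <- which(v[-1] == v[-n]) + 1L
    guard <- 0L
    while (length(bad) && guard < 10L * n) {
      i <- bad[1]
      cand <- which(v != v[i - 1] & v != v[i] & seq_len(n) > i)
      cand <- cand[vapply(cand, function(j) {
        okj <- (j == n || v[j + 1] != v[i]) && v[j - 1] != v[i]
        oki <- v[i - 1] != v[j] && (i == n || v[i + 1] != v[j])
        okj && oki
      }, logical(1))]
      if (!length(cand)) break
      j <- cand[1]
      tmp <- v[i]; v[i] <- v[j]; v[j] <- tmp
      tmp <- ord[i]; ord[i] <- ord[j]; ord[j] <- tmp
      bad <- which(v[-1] == v[-n]) + 1L
      guard <- guard + 1L
    }
    if (!length(which(v[-1] == v[-n])))
      return(ord)
  }
  stop("prepare_pairs: failed to find a no-repeat presentation order",
       call. = FALSE)
}

#' Run the recursive-least-squares filter
#'
#' Canonical exponentially weighted RLS on the flattened label vectors.
#' The inverse-correlation matrix starts at \code{(1/delta_inv) * I} and is
#' maintained with forgetting \code{beta}; each pair updates the kernel by
#' gain times the prediction error, with optional leakage \code{mu}. Every
#' \code{Q} updates the inverse-correlation matrix is re-symmetrized
#' (numerical guard). The final kernel after the last pair is returned.
#' With \code{beta = 1}, \code{mu = 0} the result equals the ridge
#' least-squares solution with regularization \code{delta_inv}.
#'
#' @param pairs An \code{\link{prepare_pairs}} result.
#' @param config An \code{\link{af_config}}.
#' @return An \code{\link{rffg}} with estimator \code{"AF"} (units: Hz per
#'   unit label when multiplied and rectified); annotation \code{rmse} is
#'   the final-kernel prediction RMSE over the pairs.
#' @export
run_rls <- function(pairs, config = af_config()) {
  X <- pairs$X; y <- pairs$y
  n <- nrow(X); d <- ncol(X)
  if (n < 1) stop("run_rls: no pairs", call. = FALSE)
  w <- numeric(d)
  P <- diag(1 / config$delta_inv, d)
  beta <- config$beta; mu <- config$mu
  for (i in seq_len(n)) {
    x <- X[i, ]
    Px <- P %*% x
    k <- Px / (beta + sum(x * Px))
    e <- y[i] - sum(w * x)
    w <- (1 - mu) * w + as.vector(k) * e
    P <- (P - tcrossprod(as.vector(k), as.vector(crossprod(x, P)))) / beta
    if (i %% config$Q == 0L && beta < 1) {
      # Re-regularization guard: with forgetting, directions not recently
      # excited make P blow up (covariance wind-up); adding delta_inv to
      # the correlation matrix caps P at its initial scale and leaves
      # well-conditioned directions essentially untouched.
      P <- (P + t(P)) / 2
      P <- chol2inv(chol(chol2inv(chol(P)) + diag(config$delta_inv, d)))
    } else if (i %% config$Q == 0L) {
      P <- (P + t(P)) / 2
    }
    if (!all(is.finite(P))) {
      warning("run_rls: inverse-correlation matrix diverged; restarting with regularization",
              call. = FALSE)
      P <- diag(1 / config$delta_inv, d)
      if (!all(is.finite(w)))
        stop("run_rls: numerically singular update", call. = FALSE)
    }
  }
  rmse <- sqrt(mean((as.vector(X %*% w) - y)^2))
  rffg(matrix(w, pairs$grid_size, pairs$grid_size), estimator = "AF",
       rmse = rmse, config = unclass(config))
}

#' Adaptive-filter kernel estimate
#'
#' Convenience wrapper: \code{\link{prepare_pairs}} then
#' \code{\link{run_rls}}.
#'
#' @inheritParams prepare_pairs
#' @return An \code{\link{rffg}} with estimator \code{"AF"}.
#' @export
rffg_af <- function(labels, spikes, config = af_config()) {
  run_rls(prepare_pairs(labels, spikes, config), config)
}
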