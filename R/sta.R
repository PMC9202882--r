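# Bias-compensated spike-triggered average (STA), its permutation
# significance, the convergence diagnostic, and the ideal-kernel reference.

#' Bias-compensated spike-triggered average
#'
#' Estimates the figure-ground responsive field as the spike-count-weighted
#' mean of the FG labels minus the ensemble-mean label:
#' \deqn{K = \frac{\sum_i L_i \, s_i}{\sum_i s_i} - \frac{\sum_i L_i}{N},}
#' where \eqn{L_i} is label i's grid and \eqn{s_i} the per-stimulus spike
#' total (sum over trials). The subtraction cancels the bias introduced by
#' the non-uniform label ensemble: a neuron responding equally to every
#' stimulus yields an exactly zero kernel, and scaling all counts by a
#' positive constant leaves the estimate unchanged.
#'
#' @param labels An \code{\link{stimulus_set}}.
#' @param spikes An \code{\link{spike_table}} covering every stimulus.
#' @param n_perm Permutation count for the magnitude significance test
#'   (default 1000; 0 skips the test).
#' @param convergence Compute the subset-size convergence diagnostic
#'   (default \code{FALSE}).
#' @param step,reps Subset-size step and repetitions for the convergence
#'   curve (defaults 20 and 100).
#' @param seed Integer seed for the permutation and subset draws.
#' @return An \code{\link{rffg}} with estimator \code{"STA"}; values lie in
#'   [-1, +1]. \code{p_perm} and \code{convergence_ratio} are filled when
#'   requested, and \code{effective} when both are.
#' @export
rffg_sta <- function(labels, spikes, n_perm = 1000, convergence = FALSE,
                     step = 20, reps = 100, seed = 1L) {
  stopifnot(inherits(labels, "fg_stimset"))
  s <- spike_totals(spikes, names(labels$labels))
  if (sum(s) <= 0)
    stop("rffg_sta: all spike counts are zero", call. = FALSE)
  grid <- sta_grid(label_matrix(labels), s, labels$grid_size)
  p <- NA_real_
  if (n_perm > 0)
    p <- sta_permutation_test(labels, spikes, n_perm = n_perm, seed = seed)
  cr <- NA_real_
  if (convergence) {
    curve <- convergence_curve(labels, spikes, step = step, reps = reps,
                               seed = seed + 1L)
    cr <- fit_convergence(curve)$ratio
  }
  rffg(grid, estimator = "STA", p_perm = p, convergence_ratio = cr)
}

# Core estimator on the stacked label matrix (N x G^2) and totals s.
sta_grid <- function(Lm, s, G) {
  k <- as.vector(crossprod(Lm, s)) / sum(s) - colMeans(Lm)
  matrix(k, G, G)
}

#' Permutation test of STA magnitude
#'
#' Shuffles the stimulus-to-spike-count assignment \code{n_perm} times,
#' recomputes the STA magnitude (squared sum of elements) for each shuffle,
#' and returns the add-one p-value
#' \eqn{p = (1 + \#\{m^* \ge m\}) / (n_{perm} + 1)}. Degenerate tables with
#' equal counts for every stimulus give p = 1 by construction.
#'
#' @inheritParams rffg_sta
#' @param n_perm Number of permutations (default 1000).
#' @return p-value in (0, 1]; the kernel is significant at p < 0.05.
#' @export
sta_permutation_test <- function(labels, spikes, n_perm = 1000, seed = 1L) {
  stopifnot(inherits(labels, "fg_stimset"), n_perm >= 1)
  s <- spike_totals(spikes, names(labels$labels))
  if (sum(s) <= 0)
    stop("sta_permutation_test: all spike counts are zero", call. = FALSE)
  Lm <- label_matrix(labels)
  obs <- sum(sta_grid(Lm, s, labels$grid_size)^2)
  set.seed(seed)
  P <- vapply(seq_len(n_perm), function(i) sample(s), numeric(length(s)))
  K <- crossprod(Lm, P) / sum(s) - colMeans(Lm)   # G^2 x n_perm
  mags <- colSums(K^2)
  (1 + sum(mags >= obs)) / (n_perm + 1)
}

#' Convergence curve of STA magnitude over subset size
#'
#' Recomputes the STA on random without-replacement label subsets of
#' increasing size (multiples of \code{step} up to N) and averages the
#' kernel magnitude over \code{reps} draws per size. The ensemble-mean
#' label is recomputed on each subset so the bias term matches the ensemble
#' actually averaged.
#'
#' @inheritParams rffg_sta
#' @param step Subset-size step (default 20).
#' @param reps Repetitions per size (default 100).
#' @return Data frame of class \code{"fg_convcurve"} with columns
#'   \code{size} and \code{magnitude}; attribute \code{N} holds the full
#'   set size.
#' @export
convergence_curve <- function(labels, spikes, step = 20, reps = 100,
                              seed = 1L) {
  stopifnot(inherits(labels, "fg_stimset"), step >= 1, reps >= 1)
  s <- spike_totals(spikes, names(labels$labels))
  Lm <- label_matrix(labels)
  N <- labels$N
  sizes <- unique(c(seq(step, N, by = step), N))
  set.seed(seed)
  mag_one <- function(idx) {
    w <- s[idx]
    k <- as.vector(crossprod(Lm[idx, , drop = FALSE], w)) / sum(w) -
      colMeans(Lm[idx, , drop = FALSE])
    sum(k^2)
  }
  mags <- vapply(sizes, function(n) {
    if (n == N) return(mag_one(seq_len(N)))
    mean(vapply(seq_len(reps), function(r) {
      for (try in 1:100) {
        idx <- sample.int(N, n)
        if (sum(s[idx]) > 0) return(mag_one(idx))
      }
      stop("convergence_curve: could not draw a subset with spikes",
           call. = FALSE)
    }, numeric(1)))
  }, numeric(1))
  structure(data.frame(size = sizes, magnitude = mags),
            class = c("fg_convcurve", "data.frame"), N = N)
}

#' Fit the saturating convergence model and compute the convergence ratio
#'
#' Fits the six-parameter saturating family
#' \deqn{y(x) = a\,(1 - b\,e^{-(x/c)^d} + b\,e)^f}
#' to the magnitude-vs-size curve by constrained nonlinear least squares
#' (multi-start Levenberg-Marquardt, box constraints keeping the curve
#' positive and \eqn{a} the asymptote). \eqn{a} is the convergent magnitude
#' at infinite set size; the convergence ratio is \eqn{y(N)/a}, clamped to
#' (0, 1]. A kernel converged well if the ratio is at least 0.9.
#'
#' @param curve A \code{"fg_convcurve"} (or data frame with \code{size},
#'   \code{magnitude}).
#' @param N Full set size (defaults to the curve's \code{N} attribute or
#'   max size).
#' @return Object of class \code{"fg_convergence"}: \code{par} (named
#'   a..f), \code{ratio}, \code{convergent} (ratio >= 0.9), \code{fitted},
#'   \code{curve}, \code{rss}.
#' @export
fit_convergence <- function(curve, N = NULL) {
  x <- curve$size; y <- curve$magnitude
  if (length(x) < 6)
    stop("fit_convergence: need at least 6 curve points", call. = FALSE)
  if (is.null(N)) N <- if (!is.null(attr(curve, "N"))) attr(curve, "N")
                       else max(x)
  fmodel <- function(p, x)
    p[1] * pmax(1 - p[2] * exp(-(x / p[3])^p[4]) + p[2] * p[5], 1e-12)^p[6]
  resid_fn <- function(p) fmodel(p, x) - y
  lower <- c(a = 1e-12, b = 0, c = 1e-6, d = 0.1, e = 0, f = 0.1)
  upper <- c(a = Inf, b = 1, c = 100 * N, d = 5, e = 0.5, f = 5)
  ylast <- max(y[length(y)], 1e-10)
  starts <- expand.grid(a = ylast, b = c(0.3, 0.9), c = c(N / 3, N),
                        d = c(0.7, 1.5), e = 0.01, f = 1)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = as.numeric(starts[i, ]), fn = resid_fn,
                         lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss)
      best <- list(par = fit$par, rss = rss)
  }
  if (is.null(best))
    stop("fit_convergence: nonlinear fit failed from all starts",
         call. = FALSE)
  p <- best$par
  names(p) <- c("a", "b", "c", "d", "e", "f")
  if (p[["a"]] <= 0)
    stop("fit_convergence: rejected fit (a <= 0)", call. = FALSE)
  ratio <- max(min(fmodel(p, N) / p[["a"]], 1), 1e-12)
  structure(list(par = p, ratio = ratio, convergent = ratio >= 0.9,
                 fitted = fmodel(p, x), curve = curve, rss = best$rss,
                 N = N),
            class = "fg_convergence")
}

#' @export
print.fg_convergence <- function(x, ...) {
  cat(sprintf("<fg_convergence> a = %.4g, ratio y(N)/a = %.3f (%s), rss = %.3g\n",
              x$par[["a"]], x$ratio,
              if (x$convergent) "converged" else "not converged", x$rss))
  invisible(x)
}

#' Ideal figure-ground kernel
#'
#' The reference kernel of an ideal FG cell: a hypothetical neuron that
#' fires exactly one spike whenever its preferred side (figure or ground)
#' covers its CRF-center cell and none otherwise. Its STA equals the mean
#' of the labels with the preferred side at the CRF center minus the
#' ensemble mean. On boundary-through-center ensembles it shows the
#' antagonistic structure: a preferred subregion on the CRF side of the
#' patch center and a non-preferred subregion opposite.
#'
#' @param labels An \code{fg_stimset}.
#' @param crf A \code{\link{crf}} locating the CRF center.
#' @param preference \code{"figure"} or \code{"ground"}.
#' @return An \code{rffg} with estimator \code{"ideal"}.
#' @export
ideal_rffg <- function(labels, crf, preference = c("figure", "ground")) {
  preference <- match.arg(preference)
  stopifnot(inherits(labels, "fg_stimset"))
  cls <- vapply(labels$labels, classify_stimulus_fg, character(1), crf = crf)
  if (!all(c("figure", "ground") %in% cls))
    stop("ideal_rffg: need stimuli of both classes at the CRF center",
         call. = FALSE)
  sel <- names(cls)[cls == preference]
  grids <- lapply(labels$labels[sel], `[[`, "grid")
  grid <- Reduce(`+`, grids) / length(grids) - labels$mean_label
  rffg(grid, estimator = "ideal", preference = preference)
}
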