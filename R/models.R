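# Rectified response models built from the estimated kernels: the STA
# model (one weighted kernel, half-wave rectified) and the STA+STC model
# (STA drive plus weighted significant STC kernels, positive-eigenvalue
# terms added and negative-eigenvalue terms subtracted, then rectified).

#' STA-model response to one label
#'
#' \code{max(0, w * <kernel, label>)}: the label is multiplied pixelwise
#' with the kernel, summed, weighted and half-wave rectified.
#'
#' @param kernel An \code{rffg} or matrix.
#' @param label An \code{fg_label} or matrix.
#' @param w Non-negative weight.
#' @return Predicted spike rate (scalar).
#' @export
sta_model_response <- function(kernel, label, w) {
  k <- if (inherits(kernel, "rffg")) kernel$grid else kernel
  l <- if (inherits(label, "fg_label")) label$grid else label
  max(0, w * sum(k * l))
}

# Per-stimulus neural rates: mean over trials of stimulus-window counts.
neural_rates <- function(spikes, ids) {
  mn <- tapply(spikes$stim_count, spikes$stimulus_id, mean)
  as.numeric(mn[ids])
}

# Pearson correlation that tolerates a constant vector (returns 0).
safe_cor <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
  stats::cor(a, b)
}

#' Fit the STA model
#'
#' Optimizes the single weight \code{w >= 0} of the rectified STA model to
#' minimize the RMS error between model responses and per-stimulus mean
#' neural rates.
#'
#' @param kernel The STA \code{rffg} (or matrix).
#' @param labels An \code{fg_stimset}.
#' @param spikes Matching \code{fg_spikes}.
#' @return Object of class \code{"fg_model"}: \code{w_sta},
#'   \code{w_stc_pos}, \code{w_stc_neg} (empty), \code{rmse},
#'   \code{pearson_r}, \code{model} = \code{"STA"}, \code{predicted},
#'   \code{observed}. A kernel driving no stimulus is flagged
#'   \code{degenerate}.
#' @export
fit_sta_model <- function(kernel, labels, spikes) {
  k <- if (inherits(kernel, "rffg")) as.vector(kernel$grid) else
    as.vector(kernel)
  Lm <- label_matrix(labels)
  drive <- as.vector(Lm %*% k)
  y <- neural_rates(spikes, names(labels$labels))
  degenerate <- all(drive <= 0)
  rmse_fn <- function(w) sqrt(mean((pmax(0, w * drive) - y)^2))
  # The rectified 1-D objective is piecewise smooth; optimize on a bracket
  # around the least-squares scale of the positive-drive subset.
  pos <- drive > 0
  w0 <- if (any(pos) && sum(drive[pos]^2) > 0)
    max(sum(drive[pos] * y[pos]) / sum(drive[pos]^2), 0) else 0
  upper <- max(1, 10 * w0)
  opt <- stats::optimize(rmse_fn, c(0, upper))
  if (rmse_fn(w0) < opt$objective) opt <- list(minimum = w0,
                                               objective = rmse_fn(w0))
  pred <- pmax(0, opt$minimum * drive)
  structure(list(w_sta = opt$minimum, w_stc_pos = numeric(0),
                 w_stc_neg = numeric(0), rmse = opt$objective,
                 pearson_r = safe_cor(pred, y), model = "STA",
                 predicted = pred, observed = y, degenerate = degenerate),
            class = "fg_model")
}

#' Fit the STA+STC model
#'
#' Drive = \code{w_sta <STA, label> + sum_j w+_j <STC+_j, label> -
#' sum_k w-_k <STC-_k, label>}, half-wave rectified. All weights are
#' optimized jointly (bounded quasi-Newton, \code{w_sta >= 0}, STC weights
#' unconstrained) from the initial point (STA-model optimum, STC weights
#' zero), so the fit can never have a larger RMSE than the STA model.
#' With no significant STC kernels the STA fit is returned unchanged.
#'
#' @param sta_kernel The STA \code{rffg} (or matrix).
#' @param stc An \code{\link{rffg_stc}} whose \code{significant} flags have
#'   been filled by \code{\link{significant_stcs}}.
#' @param labels,spikes As in \code{\link{fit_sta_model}}.
#' @return An \code{"fg_model"} with \code{model = "STA+STC"} and the
#'   per-kernel STC weights; falls back to the STA fit (with a warning and
#'   \code{fallback = TRUE}) if the optimizer fails.
#' @export
fit_sta_stc_model <- function(sta_kernel, stc, labels, spikes) {
  sta_fit <- fit_sta_model(sta_kernel, labels, spikes)
  sig <- which(isTRUE_vec(stc$significant))
  if (!length(sig)) {
    sta_fit$model <- "STA+STC"
    return(sta_fit)
  }
  k <- if (inherits(sta_kernel, "rffg")) as.vector(sta_kernel$grid) else
    as.vector(sta_kernel)
  Lm <- label_matrix(labels)
  y <- neural_rates(spikes, names(labels$labels))
  drive_sta <- as.vector(Lm %*% k)
  pos_idx <- sig[stc$eigenvalues[sig] > 0]
  neg_idx <- sig[stc$eigenvalues[sig] <= 0]
  Dpos <- if (length(pos_idx))
    Lm %*% stc$eigenvectors[, pos_idx, drop = FALSE] else NULL
  Dneg <- if (length(neg_idx))
    Lm %*% stc$eigenvectors[, neg_idx, drop = FALSE] else NULL
  np <- length(pos_idx); nn <- length(neg_idx)
  obj <- function(par) {
    drive <- par[1] * drive_sta
    if (np) drive <- drive + as.vector(Dpos %*% par[1 + seq_len(np)])
    if (nn) drive <- drive - as.vector(Dneg %*% par[1 + np + seq_len(nn)])
    sqrt(mean((pmax(0, drive) - y)^2))
  }
  # Two starts: the prescribed one (STA optimum, STC weights zero) and a
  # coordinate-wise rectified-LS scale for each STC kernel. The second is
  # needed because on sign-swap-closed ensembles the zero vector is a
  # stationary point of the symmetric numerical gradient (every label has
  # its negation in the set), where quasi-Newton iterations stall.
  ls_scale <- function(D) {
    apply(D, 2, function(p) {
      pp <- pmax(p, 0)
      if (sum(pp^2) == 0) 0 else max(0, sum(pp * y) / sum(pp^2))
    })
  }
  par0 <- c(sta_fit$w_sta, rep(0, np + nn))
  par1 <- c(sta_fit$w_sta,
            if (np) ls_scale(Dpos) else numeric(0),
            if (nn) -ls_scale(-Dneg) else numeric(0))
  fit <- NULL
  for (p0 in list(par0, par1)) {
    f <- tryCatch(
      stats::optim(p0, obj, method = "L-BFGS-B",
                   lower = c(0, rep(-Inf, np + nn)),
                   control = list(maxit = 500, factr = 1e4)),
      error = function(e) NULL)
    if (!is.null(f) && (is.null(fit) || f$value < fit$value)) fit <- f
  }
  if (is.null(fit) || fit$value > sta_fit$rmse + 1e-12) {
    if (is.null(fit))
      warning("fit_sta_stc_model: optimizer failed; returning the STA-only fit",
              call. = FALSE)
    out <- sta_fit
    out$model <- "STA+STC"
    out$fallback <- is.null(fit)
    return(out)
  }
  par <- fit$par
  drive <- par[1] * drive_sta
  if (np) drive <- drive + as.vector(Dpos %*% par[1 + seq_len(np)])
  if (nn) drive <- drive - as.vector(Dneg %*% par[1 + np + seq_len(nn)])
  pred <- pmax(0, drive)
  structure(list(w_sta = par[1],
                 w_stc_pos = par[1 + seq_len(np)],
                 w_stc_neg = par[1 + np + seq_len(nn)],
                 rmse = fit$value, pearson_r = safe_cor(pred, y),
                 model = "STA+STC", predicted = pred, observed = y,
                 degenerate = FALSE),
            class = "fg_model")
}

isTRUE_vec <- function(x) !is.na(x) & x

#' @export
print.fg_model <- function(x, ...) {
  cat(sprintf("<fg_model %s> rmse = %.4g, pearson r = %.3f, w_sta = %.4g",
              x$model, x$rmse, x$pearson_r, x$w_sta))
  if (length(x$w_stc_pos) || length(x$w_stc_neg))
    cat(sprintf(", %d STC+ / %d STC- kernels",
                length(x$w_stc_pos), length(x$w_stc_neg)))
  cat("\n")
  invisible(x)
}

#' @export
predict.fg_model <- function(object, ...) object$predicted

#' @export
residuals.fg_model <- function(object, ...) object$observed - object$predicted

#' Bayesian linearity diagnostic
#'
#' Ranks the stimuli by their normalized inner product with the kernel,
#' splits them into equal-count bins, and compares the per-bin stimulus
#' probability P(stimulus) with the spike-weighted probability
#' P(stimulus|spike). Their ratio is proportional to P(spike|stimulus),
#' the predicted rate per projection bin: a linear kernel gives a linearly
#' increasing curve (high R^2 of the regression on bin rank), an energy
#' mechanism a U-shaped one.
#'
#' @param kernel An \code{rffg} or matrix.
#' @param labels An \code{fg_stimset}.
#' @param spikes Matching \code{fg_spikes}.
#' @param n_bins Number of equal-count bins (>= 3, default 10).
#' @return Object of class \code{"fg_linearity"}: data frame \code{curve}
#'   (bin, p_stim, p_stim_spike, ratio), \code{r_squared} of the linear
#'   regression of ratio on bin rank, \code{slope}.
#' @export
linearity_diagnostic <- function(kernel, labels, spikes, n_bins = 10) {
  stopifnot(n_bins >= 3)
  k <- if (inherits(kernel, "rffg")) as.vector(kernel$grid) else
    as.vector(kernel)
  Lm <- label_matrix(labels)
  proj <- as.vector(Lm %*% k) / sqrt(sum(k^2))
  s <- spike_totals(spikes, names(labels$labels))
  ord <- order(proj)   # ties broken by stable stimulus order
  bin <- as.integer(cut(seq_along(ord), n_bins, labels = FALSE))
  p_stim <- tapply(rep(1, length(ord)), bin, sum) / length(ord)
  tot <- sum(s)
  if (tot <= 0) stop("linearity_diagnostic: no spikes", call. = FALSE)
  p_stim_spike <- tapply(s[ord], bin, sum) / tot
  ratio <- as.numeric(p_stim_spike / p_stim)
  xb <- seq_len(n_bins)
  r2 <- if (stats::sd(ratio) == 0) 0 else stats::cor(xb, ratio)^2
  slope <- if (stats::sd(ratio) == 0) 0 else
    stats::cov(xb, ratio) / stats::var(xb)
  structure(list(curve = data.frame(bin = xb,
                                    p_stim = as.numeric(p_stim),
                                    p_stim_spike = as.numeric(p_stim_spike),
                                    ratio = ratio),
                 r_squared = r2, slope = slope),
            class = "fg_linearity")
}

#' @export
print.fg_linearity <- function(x, ...) {
  cat(sprintf("<fg_linearity> %d bins, linear R^2 = %.3f, slope = %.3g\n",
              nrow(x$curve), x$r_squared, x$slope))
  invisible(x)
}
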