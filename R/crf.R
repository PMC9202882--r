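# Classical receptive field (CRF) geometry: 2D-Gaussian fitting of
# position-mapped spike counts, figure/ground classification of stimuli at
# the CRF center, and the responsiveness / FG-modulation screens.

#' Classical receptive field geometry
#'
#' The CRF is summarized by an elliptical 2D Gaussian: center (row, col) in
#' cell units, major/minor standard deviations, orientation of the major
#' axis, amplitude and baseline. Its spatial extent is the 1-SD ellipse.
#'
#' @param center Numeric length-2: (row, col), 0-based cell units.
#' @param sd_major,sd_minor Standard deviations in cells; reordered (with
#'   the orientation rotated by pi/2) so that sd_major >= sd_minor > 0.
#' @param orientation Major-axis orientation in radians, wrapped to
#'   [0, pi).
#' @param amplitude,baseline Peak height above baseline and baseline, in
#'   spikes.
#' @return Object of class \code{"crf"}.
#' @export
crf <- function(center, sd_major, sd_minor, orientation = 0,
                amplitude = 1, baseline = 0) {
  if (sd_minor > sd_major) {
    tmp <- sd_major; sd_major <- sd_minor; sd_minor <- tmp
    orientation <- orientation + pi / 2
  }
  if (sd_minor <= 0) stop("crf: SDs must be positive", call. = FALSE)
  structure(list(center = as.numeric(center), sd_major = sd_major,
                 sd_minor = sd_minor,
                 orientation = orientation %% pi,
                 amplitude = amplitude, baseline = baseline),
            class = "crf")
}

#' @export
print.crf <- function(x, ...) {
  cat(sprintf(
    "<crf> center (%.2f, %.2f), SD %.2f x %.2f cells, orientation %.2f rad, amp %.3g, base %.3g\n",
    x$center[1], x$center[2], x$sd_major, x$sd_minor, x$orientation,
    x$amplitude, x$baseline))
  invisible(x)
}

# Gaussian surface at (row, col) coordinate vectors, parameter vector
# p = (r0, c0, sd_major, sd_minor, theta, amplitude, baseline).
crf_surface <- function(p, r, c) {
  dr <- r - p[1]; dc <- c - p[2]
  u <- cos(p[5]) * dc + sin(p[5]) * dr
  v <- -sin(p[5]) * dc + cos(p[5]) * dr
  p[7] + p[6] * exp(-(u^2 / (2 * p[3]^2) + v^2 / (2 * p[4]^2)))
}

#' Probe positions of a square mapping grid
#'
#' Cell-unit coordinates of an n x n grid of grating probe positions
#' spanning the stimulus extent.
#'
#' @param grid_size Stimulus grid size G.
#' @param n Probes per side (default 5).
#' @return List of two n x n matrices, \code{row} and \code{col}.
#' @export
grating_positions <- function(grid_size = 25, n = 5) {
  s <- seq(0, grid_size - 1, length.out = n)
  list(row = matrix(rep(s, times = n), n, n),
       col = matrix(rep(s, each = n), n, n))
}

#' Fit CRF geometry to a spike-count map
#'
#' Least-squares fit of an elliptical 2D Gaussian (center, two SDs,
#' orientation, amplitude, baseline) to mean spike counts observed at a
#' grid of probe positions. Levenberg-Marquardt with box constraints and up
#' to 5 starts seeded from the map's peak cell and second moments; the
#' best-RSS fit is returned.
#'
#' @param map Numeric matrix of mean spike counts (typically 5 x 5).
#' @param positions List with matrices \code{row} and \code{col} matching
#'   \code{map}; defaults to \code{\link{grating_positions}} spanning a
#'   25-cell grid.
#' @return A \code{\link{crf}}; attribute \code{rss} carries the residual
#'   sum of squares and attribute \code{degenerate} flags a flat map
#'   (relative amplitude below 1e-6).
#' @export
fit_crf <- function(map, positions = grating_positions(25, nrow(map))) {
  ok <- is.finite(map)
  if (sum(ok) < 7)
    stop("fit_crf: need at least 7 finite map entries", call. = FALSE)
  r <- positions$row[ok]; c <- positions$col[ok]; z <- map[ok]
  span <- max(max(r) - min(r), max(c) - min(c))
  peak <- which.max(map)
  pk <- c(positions$row[peak], positions$col[peak])
  base0 <- min(z); amp0 <- max(z) - base0
  if (amp0 <= 0) amp0 <- 1e-6
  w <- pmax(z - base0, 0); sw <- sum(w)
  sd0 <- if (sw > 0)
    sqrt(sum(w * ((r - sum(w * r) / sw)^2 + (c - sum(w * c) / sw)^2)) /
           (2 * sw))
  else span / 4
  sd0 <- min(max(sd0, 0.3), span)
  lower <- c(min(r) - span, min(c) - span, 0.05, 0.05, -pi, 0, -Inf)
  upper <- c(max(r) + span, max(c) + span, 4 * span, 4 * span, pi, Inf, Inf)
  starts <- list(
    c(pk, sd0, sd0, 0, amp0, base0),
    c(pk, sd0 * 1.5, sd0 * 0.7, pi / 4, amp0, base0),
    c(pk, sd0 * 1.5, sd0 * 0.7, -pi / 4, amp0, base0),
    c(pk, sd0 * 0.5, sd0 * 0.5, 0, amp0, base0),
    c(mean(r), mean(c), span / 2, span / 2, 0, amp0, base0))
  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, fn = function(p) crf_surface(p, r, c) - z,
                         lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 400, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(par = fit$par, rss = rss)
  }
  if (is.null(best))
    stop("fit_crf: Gaussian fit failed from all starts", call. = FALSE)
  p <- best$par
  out <- crf(center = p[1:2], sd_major = p[3], sd_minor = p[4],
             orientation = p[5], amplitude = p[6], baseline = p[7])
  attr(out, "rss") <- best$rss
  attr(out, "degenerate") <- p[6] <= 1e-6 * max(abs(z), 1e-12)
  if (attr(out, "degenerate"))
    warning("fit_crf: flat map; amplitude ~ 0, geometry is unreliable",
            call. = FALSE)
  out
}

#' Classify a stimulus as figure-at-CRF or ground-at-CRF
#'
#' Reads the label sign at the cell nearest the CRF center: +1 is
#' \code{"figure"}, -1 \code{"ground"}. Halfway coordinates round toward
#' the higher index (deterministic).
#'
#' @param label An \code{\link{fg_label}}.
#' @param crf A \code{\link{crf}} with center inside the grid.
#' @return \code{"figure"} or \code{"ground"}.
#' @export
classify_stimulus_fg <- function(label, crf) {
  g <- label$grid; G <- nrow(g)
  rc <- floor(crf$center + 0.5)   # nearest cell, 0-based
  if (any(rc < 0) || any(rc > G - 1))
    stop("classify_stimulus_fg: CRF center outside the grid", call. = FALSE)
  v <- g[rc[1] + 1, rc[2] + 1]
  if (v == 0)
    stop(sprintf("classify_stimulus_fg: CRF center on a masked cell of '%s'",
                 label$stimulus_id), call. = FALSE)
  if (v > 0) "figure" else "ground"
}

#' Responsiveness screen
#'
#' Compares pooled pre-stimulus counts against pooled stimulus-window
#' counts across all trials and stimuli. A two-sided F-test at alpha = 0.05
#' selects Student's t-test (equal variances) or Welch's t-test; the neuron
#' is responsive at p < 0.05.
#'
#' @param spikes An \code{fg_spikes} table.
#' @return Two-sided p-value; attributes \code{method} (\code{"student"} /
#'   \code{"welch"} / \code{"degenerate"}) and \code{responsive}. Zero
#'   variance in both samples gives p = 1 flagged degenerate.
#' @export
responsiveness_test <- function(spikes) {
  pre <- spikes$pre_count; stim <- spikes$stim_count
  if (length(pre) < 2)
    stop("responsiveness_test: need at least 2 trials", call. = FALSE)
  if (stats::var(pre) == 0 && stats::var(stim) == 0) {
    p <- 1
    attr(p, "method") <- "degenerate"
    attr(p, "responsive") <- FALSE
    return(p)
  }
  equal_var <- if (stats::var(pre) == 0 || stats::var(stim) == 0) FALSE
  else stats::var.test(stim, pre)$p.value >= 0.05
  tt <- stats::t.test(stim, pre, var.equal = equal_var)
  p <- tt$p.value
  attr(p, "method") <- if (equal_var) "student" else "welch"
  attr(p, "responsive") <- p < 0.05
  p
}

#' Figure-ground modulation screen (one-way ANOVA)
#'
#' One-way ANOVA of per-stimulus mean spike counts grouped by the
#' figure-at-CRF / ground-at-CRF classification; modulation is significant
#' at p < 0.05. In the two-class case the F statistic equals the squared
#' two-sample (pooled) t statistic.
#'
#' @param spikes An \code{fg_spikes} table.
#' @param classes Named character vector (\code{"figure"}/\code{"ground"})
#'   keyed by stimulus id.
#' @return p-value with attribute \code{significant}.
#' @export
fg_modulation_anova <- function(spikes, classes) {
  mn <- tapply(spikes$stim_count, spikes$stimulus_id, mean)
  cls <- classes[names(mn)]
  if (any(is.na(cls)))
    stop("fg_modulation_anova: classes missing for some stimuli",
         call. = FALSE)
  if (any(table(cls) < 2))
    stop("fg_modulation_anova: each class needs at least 2 stimuli",
         call. = FALSE)
  fit <- stats::aov(mn ~ factor(cls))
  p <- summary(fit)[[1]][["Pr(>F)"]][1]
  attr(p, "significant") <- p < 0.05
  p
}
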