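# Synthetic stimulus ensembles and virtual neurons with known ground-truth
# kernels. These generators reproduce the structural constraints of the
# stimulus design -- boundaries through the patch center, figure/ground
# mirror pairs, exhaustive +/-1 dot probes -- so every estimator can be
# validated without recorded data.

# Cell-center offsets from the grid center, 0-based convention:
# offset = index - (G-1)/2, in cell units. Rows increase downward.
cell_offsets <- function(G) {
  o <- seq_len(G) - 1 - (G - 1) / 2
  list(dr = matrix(rep(o, times = G), G, G),
       dc = matrix(rep(o, each = G), G, G))
}

#' Half-plane label ensemble
#'
#' For each of \code{n_orientations} uniformly spaced boundary orientations
#' in [0, pi), two labels whose boundary is a straight line through the
#' grid center, with figure on either side (mirror pairs, exact
#' negations). Cells whose center lies exactly on the boundary go to the
#' figure side of the primary label. The ensemble mean is exactly zero.
#'
#' @param n_orientations Number of orientations (>= 2).
#' @param grid_size Grid size G (default 25).
#' @return An \code{\link{stimulus_set}} with \code{2 * n_orientations}
#'   labels and mirror_partner links.
#' @export
gen_halfplane_labels <- function(n_orientations, grid_size = 25) {
  if (n_orientations < 2)
    stop("gen_halfplane_labels: need n_orientations >= 2", call. = FALSE)
  off <- cell_offsets(grid_size)
  labels <- list()
  for (k in seq_len(n_orientations)) {
    frac <- (k - 1) / n_orientations     # phi = frac * pi
    s <- off$dc * cospi(frac) + off$dr * sinpi(frac)
    gA <- ifelse(s >= 0, 1, -1)
    ia <- sprintf("hp%03da", k); ib <- sprintf("hp%03db", k)
    labels[[ia]] <- fg_label(gA, ia, "synthetic", mirror_partner = ib)
    labels[[ib]] <- fg_label(-gA, ib, "synthetic", mirror_partner = ia)
  }
  stimulus_set(labels)
}

#' Curved-boundary label ensemble
#'
#' Smooth random boundaries through the grid center: a straight line at a
#' random orientation perturbed, in the normal direction, by a cubic
#' polynomial of the tangent coordinate with zero offset at the center.
#' Because the perturbation is a function of the tangent coordinate the
#' boundary always partitions the grid into two simply connected regions.
#' Each base curve contributes a figure/ground-swapped mirror pair, so the
#' ensemble mean is exactly zero. Deterministic under \code{seed}.
#'
#' @param n Number of base curves (>= 1); the set holds \code{2n} labels.
#' @param grid_size Grid size G (default 25).
#' @param curvature_sd SD of the polynomial coefficients, in cells
#'   (0 reproduces half-planes at the drawn orientations).
#' @param seed Integer seed.
#' @param max_retries Retries per curve if a draw violates the
#'   center-boundary invariant (default 20).
#' @return An \code{\link{stimulus_set}}.
#' @export
gen_curved_labels <- function(n, grid_size = 25, curvature_sd = 2,
                              seed = 1L, max_retries = 20) {
  stopifnot(n >= 1, curvature_sd >= 0)
  set.seed(seed)
  off <- cell_offsets(grid_size)
  half <- (grid_size - 1) / 2
  labels <- list()
  for (k in seq_len(n)) {
    lab <- NULL
    for (try in seq_len(max_retries)) {
      phi <- stats::runif(1, 0, pi)
      a <- stats::rnorm(3, 0, curvature_sd)
      u <- c(cos(phi), sin(phi)); v <- c(-sin(phi), cos(phi))
      tt <- (off$dc * u[1] + off$dr * u[2]) / half
      ss <- off$dc * v[1] + off$dr * v[2]
      o <- a[1] * tt + a[2] * tt^2 + a[3] * tt^3
      g <- ifelse(ss - o >= 0, 1, -1)
      ia <- sprintf("cv%03da", k); ib <- sprintf("cv%03db", k)
      lab <- tryCatch(
        list(fg_label(g, ia, "synthetic", mirror_partner = ib),
             fg_label(-g, ib, "synthetic", mirror_partner = ia)),
        error = function(e) NULL)
      if (!is.null(lab)) break
    }
    if (is.null(lab))
      stop("gen_curved_labels: failed to draw a valid boundary after ",
           max_retries, " tries", call. = FALSE)
    labels[[lab[[1]]$stimulus_id]] <- lab[[1]]
    labels[[lab[[2]]$stimulus_id]] <- lab[[2]]
  }
  stimulus_set(labels)
}

#' Exhaustive single-cell dot stimuli
#'
#' The 2 G^2 stimuli that are zero everywhere except one cell set to +1 or
#' -1. This set is white (uncorrelated across cells) and closed under sign
#' swap, so its ensemble mean is exactly zero; it is the reference probe
#' for kernel-recovery validation.
#'
#' @param grid_size Grid size G (>= 1).
#' @return An \code{\link{stimulus_set}} of class-\code{"dot"} labels.
#' @export
gen_dot_stimuli <- function(grid_size = 25) {
  stopifnot(grid_size >= 1)
  G <- grid_size
  labels <- vector("list", 2 * G * G)
  idx <- 1L
  for (i in seq_len(G)) for (j in seq_len(G)) for (sgn in c(1, -1)) {
    g <- matrix(0, G, G); g[i, j] <- sgn
    id <- sprintf("dot%02d_%02d_%s", i - 1, j - 1, if (sgn > 0) "p" else "m")
    labels[[idx]] <- fg_label(g, id, "dot")
    idx <- idx + 1L
  }
  stimulus_set(labels)
}

#' Translated copies of a label set
#'
#' Shifts every label by each (dx, dy) offset (columns right, rows down),
#' filling cells shifted in from outside the grid with the nearest in-grid
#' value (the nearer side). Shifted copies are flagged \code{translated},
#' which waives the boundary-through-center invariant.
#'
#' @param base An \code{fg_stimset}.
#' @param shifts List of integer length-2 vectors \code{c(dx, dy)}, all
#'   smaller than the grid in magnitude.
#' @return An \code{\link{stimulus_set}}; for the single shift (0,0) the
#'   base set is returned unchanged.
#' @export
gen_translated_labels <- function(base, shifts) {
  stopifnot(inherits(base, "fg_stimset"))
  if (!is.list(shifts)) shifts <- list(shifts)
  G <- base$grid_size
  if (any(vapply(shifts, function(s) any(abs(s) >= G), logical(1))))
    stop("gen_translated_labels: shift exceeds grid", call. = FALSE)
  if (length(shifts) == 1 && all(shifts[[1]] == 0)) return(base)
  labels <- list()
  for (k in seq_along(shifts)) {
    dx <- shifts[[k]][1]; dy <- shifts[[k]][2]
    src_r <- pmin(pmax(seq_len(G) - dy, 1), G)
    src_c <- pmin(pmax(seq_len(G) - dx, 1), G)
    for (l in base$labels) {
      id <- sprintf("%s_t%02d", l$stimulus_id, k)
      labels[[id]] <- fg_label(l$grid[src_r, src_c], id, l$stimulus_class,
                               translated = (dx != 0 || dy != 0))
    }
  }
  stimulus_set(labels)
}

#' Odd-symmetric difference-of-Gaussians kernel
#'
#' A positive Gaussian lobe on one side of the center and a negative lobe
#' on the other, displaced along the orientation axis, antisymmetrized
#' about the center so that reflecting any point through the center negates
#' the value exactly, and normalized to unit Euclidean norm.
#'
#' @param center (row, col) in 0-based cell units (default: grid center).
#' @param orientation Axis of the lobes, radians.
#' @param sigma_center,sigma_surround Lobe SDs in cells (> 0).
#' @param grid_size Grid size G (default 25).
#' @return G x G numeric matrix with unit Euclidean norm.
#' @export
make_dog_kernel <- function(center = NULL, orientation = 0,
                            sigma_center = 2, sigma_surround = 4,
                            grid_size = 25) {
  stopifnot(sigma_center > 0, sigma_surround > 0)
  G <- grid_size
  if (is.null(center)) center <- c((G - 1) / 2, (G - 1) / 2)
  d <- (sigma_center + sigma_surround) / 2
  u <- c(sin(orientation), cos(orientation))   # (row, col) direction
  lobe_pos <- center + d * u
  lobe_neg <- center - d * u
  r <- matrix(rep(seq_len(G) - 1, times = G), G, G)
  c_ <- matrix(rep(seq_len(G) - 1, each = G), G, G)
  raw <- function(rr, cc)
    exp(-((rr - lobe_pos[1])^2 + (cc - lobe_pos[2])^2) /
          (2 * sigma_center^2)) -
    exp(-((rr - lobe_neg[1])^2 + (cc - lobe_neg[2])^2) /
          (2 * sigma_surround^2))
  k <- (raw(r, c_) - raw(2 * center[1] - r, 2 * center[2] - c_)) / 2
  k / sqrt(sum(k^2))
}

#' Virtual neuron with a known response rule
#'
#' Model cells used to validate the estimators:
#' \describe{
#'   \item{\code{ideal_fg}}{fires exactly 1 spike per trial when the
#'     preferred side (figure or ground) covers the CRF-center cell,
#'     0 otherwise;}
#'   \item{\code{rectified_linear}}{expected rate
#'     \code{gain * max(0, <kernel, label>)};}
#'   \item{\code{linear}}{expected rate
#'     \code{gain * (offset + <kernel, label>)}, clamped at 0 (choose
#'     \code{offset} large enough that the clamp never engages for a
#'     purely linear cell);}
#'   \item{\code{energy}}{expected rate \code{gain * |<kernel, label>|} --
#'     zero mean drive, invisible to the STA but recoverable by STC;}
#'   \item{\code{non_fg}}{a constant expected count for every stimulus.}
#' }
#'
#' @param kind Response rule (see above).
#' @param preference \code{"figure"} or \code{"ground"} (ideal_fg only).
#' @param kernel G x G matrix (kernel-driven kinds).
#' @param crf A \code{\link{crf}} (ideal_fg only).
#' @param gain Spikes per unit drive (default 1).
#' @param offset Drive offset for \code{linear} (default 0).
#' @param constant Expected count of a \code{non_fg} cell (default 1).
#' @param noise \code{"none"} (expected counts rounded to nearest integer)
#'   or \code{"poisson"}.
#' @param baseline_rate Expected pre-stimulus count per trial (default 0).
#' @return Object of class \code{"virtual_neuron"}.
#' @export
virtual_neuron <- function(kind = c("ideal_fg", "rectified_linear",
                                    "linear", "energy", "non_fg"),
                           preference = "figure", kernel = NULL, crf = NULL,
                           gain = 1, offset = 0, constant = 1,
                           noise = c("none", "poisson"),
                           baseline_rate = 0) {
  kind <- match.arg(kind)
  noise <- match.arg(noise)
  if (kind == "ideal_fg" && is.null(crf))
    stop("virtual_neuron: ideal_fg needs a crf", call. = FALSE)
  if (kind %in% c("rectified_linear", "linear", "energy") && is.null(kernel))
    stop("virtual_neuron: kernel-driven kinds need a kernel", call. = FALSE)
  structure(list(kind = kind, preference = preference,
                 kernel = if (!is.null(kernel)) as.matrix(kernel),
                 crf = crf, gain = gain, offset = offset,
                 constant = constant, noise = noise,
                 baseline_rate = baseline_rate),
            class = "virtual_neuron")
}

#' @export
print.virtual_neuron <- function(x, ...) {
  cat(sprintf("<virtual_neuron> %s (gain %.3g, noise %s)\n",
              x$kind, x$gain, x$noise))
  invisible(x)
}

# Expected stimulus-window rate of a neuron for one label grid.
neuron_rate <- function(neuron, label) {
  switch(neuron$kind,
    ideal_fg = as.numeric(
      classify_stimulus_fg(label, neuron$crf) == neuron$preference),
    rectified_linear = neuron$gain *
      max(0, sum(neuron$kernel * label$grid)),
    linear = max(0, neuron$gain *
                   (neuron$offset + sum(neuron$kernel * label$grid))),
    energy = neuron$gain * abs(sum(neuron$kernel * label$grid)),
    non_fg = neuron$constant)
}

#' Simulate a spike-count table for a virtual neuron
#'
#' Draws per-trial stimulus-window counts from the neuron's expected rate
#' (rounded when \code{noise = "none"}, Poisson otherwise) and pre-stimulus
#' counts from \code{baseline_rate}. Deterministic under \code{seed}.
#'
#' @param neuron A \code{\link{virtual_neuron}}.
#' @param labels An \code{fg_stimset} whose grid matches any neuron kernel.
#' @param n_trials Trials per stimulus (default 10).
#' @param seed Integer seed.
#' @return An \code{\link{spike_table}}.
#' @export
simulate_responses <- function(neuron, labels, n_trials = 10, seed = 1L) {
  stopifnot(inherits(neuron, "virtual_neuron"), inherits(labels, "fg_stimset"))
  if (!is.null(neuron$kernel) &&
      !all(dim(neuron$kernel) == c(labels$grid_size, labels$grid_size)))
    stop("simulate_responses: kernel grid does not match label grid",
         call. = FALSE)
  set.seed(seed)
  rates <- vapply(labels$labels, function(l) neuron_rate(neuron, l),
                  numeric(1))
  n <- labels$N
  draw <- function(mu) {
    if (neuron$noise == "poisson") stats::rpois(length(mu), mu)
    else as.integer(round(mu))
  }
  stim <- draw(rep(rates, each = n_trials))
  pre <- draw(rep(neuron$baseline_rate, n * n_trials))
  spike_table(stimulus_id = rep(names(labels$labels), each = n_trials),
              trial = rep(seq_len(n_trials), times = n),
              pre_count = pre, stim_count = stim)
}

#' Simulated grating spike-count map
#'
#' Mean spike counts at an n x n grid of probe positions, proportional to
#' the CRF Gaussian (amplitude, baseline included) times \code{gain}, with
#' optional Poisson trial noise. Used to exercise \code{\link{fit_crf}}.
#'
#' @param crf A \code{\link{crf}}.
#' @param grid_size Stimulus extent in cells (default 25).
#' @param n Probes per side (default 5).
#' @param gain Multiplier on the Gaussian rate (default 1).
#' @param n_trials Trials averaged per position (default 10).
#' @param noise \code{"none"} or \code{"poisson"}.
#' @param seed Integer seed.
#' @return List with \code{map} (n x n mean counts) and \code{positions}
#'   (as \code{\link{grating_positions}}).
#' @export
gen_grating_response_map <- function(crf, grid_size = 25, n = 5, gain = 1,
                                     n_trials = 10,
                                     noise = c("none", "poisson"),
                                     seed = 1L) {
  noise <- match.arg(noise)
  pos <- grating_positions(grid_size, n)
  p <- c(crf$center, crf$sd_major, crf$sd_minor, crf$orientation,
         crf$amplitude, crf$baseline)
  mu <- gain * crf_surface(p, pos$row, pos$col)
  map <- mu
  if (noise == "poisson") {
    set.seed(seed)
    map <- matrix(rowMeans(matrix(
      stats::rpois(n * n * n_trials, rep(pmax(as.vector(mu), 0), n_trials)),
      nrow = n * n)), n, n)
  }
  list(map = map, positions = pos)
}
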