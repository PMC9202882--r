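# Geometry and comparison metrics for estimated kernels: cosine
# similarity, PR ratio, CRF overlap, rotation and CRF-scale alignment, and
# population averaging.

#' Cosine similarity between two kernels
#'
#' Euclidean dot product of the flattened grids divided by the product of
#' their norms. Symmetric and invariant to positive scaling of either
#' argument.
#'
#' @param k1,k2 \code{rffg} objects or matrices of equal size.
#' @return Scalar in [-1, 1].
#' @export
cosine_similarity <- function(k1, k2) {
  a <- as.vector(if (inherits(k1, "rffg")) k1$grid else k1)
  b <- as.vector(if (inherits(k2, "rffg")) k2$grid else k2)
  if (length(a) != length(b))
    stop("cosine_similarity: grid sizes differ", call. = FALSE)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0)
    stop("cosine_similarity: zero-norm kernel", call. = FALSE)
  sum(a * b) / (na * nb)
}

# Supra-threshold support: cells with |value| above epsilon * max |value|.
kernel_support <- function(g, epsilon) {
  m <- max(abs(g))
  if (m == 0) stop("kernel support: all-zero kernel", call. = FALSE)
  abs(g) > epsilon * m
}

#' PR ratio: preferred-subregion share of the kernel's support
#'
#' The fraction of supra-threshold cells (|value| > epsilon * max |value|)
#' carrying the preferred sign (+ for figure preference, - for ground).
#' 0.5 indicates a balanced antagonistic kernel.
#'
#' @param kernel An \code{rffg} or matrix.
#' @param preference \code{"figure"} or \code{"ground"}.
#' @param epsilon Support threshold relative to the max (default 0.05).
#' @return Scalar in [0, 1].
#' @export
pr_ratio <- function(kernel, preference = c("figure", "ground"),
                     epsilon = 0.05) {
  preference <- match.arg(preference)
  g <- if (inherits(kernel, "rffg")) kernel$grid else kernel
  supp <- kernel_support(g, epsilon)
  if (!any(supp))
    stop("pr_ratio: no supra-threshold cells", call. = FALSE)
  pref <- if (preference == "figure") g > 0 else g < 0
  sum(supp & pref) / sum(supp)
}

# Cells whose center lies inside the CRF's 1-SD ellipse.
rasterize_crf_ellipse <- function(crf, G) {
  r <- matrix(rep(seq_len(G) - 1, times = G), G, G)
  c_ <- matrix(rep(seq_len(G) - 1, each = G), G, G)
  dr <- r - crf$center[1]; dc <- c_ - crf$center[2]
  u <- cos(crf$orientation) * dc + sin(crf$orientation) * dr
  v <- -sin(crf$orientation) * dc + cos(crf$orientation) * dr
  (u / crf$sd_major)^2 + (v / crf$sd_minor)^2 <= 1
}

#' Overlap ratio between the CRF extent and the preferred subregion
#'
#' Jaccard-style |AND| / |OR| between the rasterized 1-SD CRF ellipse
#' (cells whose center falls inside) and the kernel's preferred
#' supra-threshold subregion: 1 for identical extents, 0 for disjoint.
#' Zero-valued (masked) kernel cells are excluded.
#'
#' @param crf A \code{\link{crf}}.
#' @inheritParams pr_ratio
#' @return Scalar in [0, 1].
#' @export
overlap_ratio <- function(crf, kernel, preference = c("figure", "ground"),
                          epsilon = 0.05) {
  preference <- match.arg(preference)
  g <- if (inherits(kernel, "rffg")) kernel$grid else kernel
  ell <- rasterize_crf_ellipse(crf, nrow(g))
  supp <- kernel_support(g, epsilon)
  pref <- supp & (if (preference == "figure") g > 0 else g < 0)
  un <- sum(ell | pref)
  if (un == 0) stop("overlap_ratio: empty union", call. = FALSE)
  sum(ell & pref) / un
}

# Bilinear sample of grid g at fractional 0-based (r, c); outside -> 0.
sample_bilinear <- function(g, r, c) {
  G <- nrow(g)
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  val <- function(ri, ci) {
    ok <- ri >= 0 & ri <= G - 1 & ci >= 0 & ci <= G - 1
    out <- numeric(length(ri))
    out[ok] <- g[cbind(ri[ok] + 1, ci[ok] + 1)]
    out
  }
  val(r0, c0) * (1 - fr) * (1 - fc) + val(r0 + 1, c0) * fr * (1 - fc) +
    val(r0, c0 + 1) * (1 - fr) * fc + val(r0 + 1, c0 + 1) * fr * fc
}

# Apply an inverse coordinate map (target cell -> source position) to a
# kernel grid with bilinear interpolation.
warp_kernel <- function(g, inv_map) {
  G <- nrow(g)
  r <- matrix(rep(seq_len(G) - 1, times = G), G, G)
  c_ <- matrix(rep(seq_len(G) - 1, each = G), G, G)
  src <- inv_map(as.vector(r), as.vector(c_))
  matrix(sample_bilinear(g, src$r, src$c), G, G)
}

#' Rotate a kernel so its preferred subregion faces the reference side
#'
#' Rotates the grid about the patch center by the angle taking the
#' value-weighted center of gravity of the preferred supra-threshold
#' subregion onto the reference axis: figure subregions to the left,
#' ground subregions to the right. Bilinear interpolation; cells rotated
#' in from outside the grid are set to 0.
#'
#' @inheritParams pr_ratio
#' @return An \code{rffg} (same estimator tag); attribute \code{angle}
#'   holds the applied rotation in radians.
#' @export
rotate_align <- function(kernel, preference = c("figure", "ground"),
                         epsilon = 0.05) {
  preference <- match.arg(preference)
  is_r <- inherits(kernel, "rffg")
  g <- if (is_r) kernel$grid else kernel
  G <- nrow(g)
  ctr <- (G - 1) / 2
  supp <- kernel_support(g, epsilon)
  pref <- supp & (if (preference == "figure") g > 0 else g < 0)
  if (!any(pref))
    stop("rotate_align: empty preferred subregion", call. = FALSE)
  w <- abs(g)[pref]
  idx <- which(pref, arr.ind = TRUE) - 1
  cog <- c(sum(w * idx[, 1]), sum(w * idx[, 2])) / sum(w) - ctr
  if (sqrt(sum(cog^2)) < 1e-9)
    stop("rotate_align: center of gravity at the patch center; rotation undefined",
         call. = FALSE)
  theta_cur <- atan2(cog[1], cog[2])          # (row, col) angle
  theta_tar <- if (preference == "figure") pi else 0
  delta <- theta_tar - theta_cur
  out <- warp_kernel(g, function(r, c) {
    dr <- r - ctr; dc <- c - ctr
    list(r = ctr + sin(-delta) * dc + cos(-delta) * dr,
         c = ctr + cos(-delta) * dc - sin(-delta) * dr)
  })
  res <- if (is_r) rffg(out, estimator = kernel$estimator,
                        preference = kernel$preference)
         else rffg(out, estimator = "STA")
  attr(res, "angle") <- delta
  res
}

#' Rescale a kernel about its CRF center to a common CRF size
#'
#' Isotropically rescales the grid about the CRF center so that the
#' geometric mean of the CRF's two SDs equals \code{target_sd}. Bilinear
#' interpolation; cells scaled in from outside the grid are 0.
#'
#' @param kernel An \code{rffg} or matrix.
#' @param crf A \code{\link{crf}}.
#' @param target_sd Target geometric-mean SD in cells.
#' @return An \code{rffg}; attribute \code{factor} holds the scale factor.
#' @export
scale_by_crf <- function(kernel, crf, target_sd) {
  is_r <- inherits(kernel, "rffg")
  g <- if (is_r) kernel$grid else kernel
  gm <- sqrt(crf$sd_major * crf$sd_minor)
  if (!is.finite(gm) || gm <= 0)
    stop("scale_by_crf: degenerate CRF", call. = FALSE)
  f <- target_sd / gm
  ctr <- crf$center
  out <- warp_kernel(g, function(r, c)
    list(r = ctr[1] + (r - ctr[1]) / f, c = ctr[2] + (c - ctr[2]) / f))
  res <- if (is_r) rffg(out, estimator = kernel$estimator,
                        preference = kernel$preference)
         else rffg(out, estimator = "STA")
  attr(res, "factor") <- f
  res
}

# Translate a kernel so that the CRF center lands on the patch center.
center_on_crf <- function(g, crf) {
  G <- nrow(g); ctr <- (G - 1) / 2
  sh <- crf$center - ctr
  warp_kernel(g, function(r, c) list(r = r + sh[1], c = c + sh[2]))
}

#' Population mean of aligned kernels
#'
#' Normalizes each kernel by its own max |value|, aligns it per the chosen
#' mode, and returns the element-wise mean:
#' \describe{
#'   \item{\code{crf_centered}}{translate so the CRF center lands on the
#'     patch center (needs \code{crfs});}
#'   \item{\code{rotated}}{rotate the preferred subregion to the reference
#'     side via \code{\link{rotate_align}} (needs \code{preferences});}
#'   \item{\code{crf_scaled}}{translate to the patch center, then rescale
#'     so the geometric-mean CRF SD equals \code{target_sd} (needs
#'     \code{crfs}).}
#' }
#' Kernels whose alignment fails are excluded with a warning.
#'
#' @param kernels List of \code{rffg} objects or matrices.
#' @param mode Alignment mode (see above).
#' @param crfs List of \code{\link{crf}} per kernel.
#' @param preferences Character vector per kernel.
#' @param target_sd Target SD for \code{crf_scaled}.
#' @param epsilon Support threshold for \code{rotated}.
#' @return An \code{rffg} holding the mean grid; attribute \code{n_used}
#'   counts included kernels.
#' @export
population_mean <- function(kernels,
                            mode = c("crf_centered", "rotated", "crf_scaled"),
                            crfs = NULL, preferences = NULL,
                            target_sd = NULL, epsilon = 0.05) {
  mode <- match.arg(mode)
  if (!length(kernels)) stop("population_mean: no kernels", call. = FALSE)
  acc <- NULL; n_used <- 0L
  for (i in seq_along(kernels)) {
    g <- kernels[[i]]
    g <- if (inherits(g, "rffg")) g$grid else as.matrix(g)
    m <- max(abs(g))
    if (m == 0) { warning("population_mean: kernel ", i, " is zero; excluded",
                          call. = FALSE); next }
    g <- g / m
    ali <- tryCatch(switch(mode,
      crf_centered = center_on_crf(g, crfs[[i]]),
      rotated = rotate_align(g, preferences[[i]], epsilon)$grid,
      crf_scaled = scale_by_crf(center_on_crf(g, crfs[[i]]),
                                crf(c((nrow(g) - 1) / 2, (ncol(g) - 1) / 2),
                                    crfs[[i]]$sd_major, crfs[[i]]$sd_minor,
                                    crfs[[i]]$orientation),
                                target_sd)$grid),
      error = function(e) {
        warning("population_mean: kernel ", i, " excluded (",
                conditionMessage(e), ")", call. = FALSE)
        NULL
      })
    if (is.null(ali)) next
    acc <- if (is.null(acc)) ali else acc + ali
    n_used <- n_used + 1L
  }
  if (n_used == 0L)
    stop("population_mean: all kernels excluded", call. = FALSE)
  out <- rffg(acc / n_used, estimator = "STA")
  attr(out, "n_used") <- n_used
  out
}
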