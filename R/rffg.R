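# The common kernel container returned by all estimators.

#' Figure-ground responsive field (kernel)
#'
#' A real-valued kernel on the label grid: positive cells mark locations
#' where a figure increases the response, negative cells where a ground
#' does. Kernels carry estimator provenance and, when computed,
#' significance and convergence annotations. A kernel is \emph{effective}
#' when its magnitude is permutation-significant (p < 0.05) and its
#' convergence ratio is at least 0.9.
#'
#' @param grid G x G numeric matrix.
#' @param estimator One of \code{"STA"}, \code{"AF"}, \code{"STC"},
#'   \code{"ideal"}.
#' @param p_perm Permutation p-value of the magnitude (or \code{NA}).
#' @param convergence_ratio Convergence ratio in (0, 1] (or \code{NA}).
#' @param preference \code{"figure"}, \code{"ground"} or \code{NA}: the
#'   sign of the kernel at the CRF-center cell.
#' @param ... Extra annotations stored on the object (e.g.
#'   \code{eigenvalue} for STC kernels).
#' @return An object of class \code{"rffg"} with elements \code{grid},
#'   \code{estimator}, \code{magnitude} (sum of squared cells),
#'   \code{p_perm}, \code{convergence_ratio}, \code{effective},
#'   \code{preference}.
#' @export
rffg <- function(grid, estimator = "STA", p_perm = NA_real_,
                 convergence_ratio = NA_real_, preference = NA_character_,
                 ...) {
  grid <- as.matrix(grid)
  extra <- list(...)
  extra$magnitude <- NULL; extra$effective <- NULL
  eff <- if (is.na(p_perm) || is.na(convergence_ratio)) NA
         else (p_perm < 0.05 && convergence_ratio >= 0.9)
  structure(c(list(grid = grid, estimator = estimator,
                   magnitude = sum(grid^2), p_perm = p_perm,
                   convergence_ratio = convergence_ratio,
                   effective = eff, preference = preference),
              extra),
            class = "rffg")
}

#' Magnitude of a kernel
#'
#' The squared sum of all elements, the statistic used for permutation
#' significance.
#'
#' @param kernel An \code{rffg} or a plain matrix.
#' @return Numeric scalar.
#' @export
kernel_magnitude <- function(kernel) {
  g <- if (inherits(kernel, "rffg")) kernel$grid else kernel
  sum(g^2)
}

#' @export
print.rffg <- function(x, ...) {
  cat(sprintf("<rffg> %s kernel, %dx%d, magnitude %.4g",
              x$estimator, nrow(x$grid), ncol(x$grid), x$magnitude))
  if (!is.na(x$p_perm)) cat(sprintf(", p_perm = %.4g", x$p_perm))
  if (!is.na(x$convergence_ratio))
    cat(sprintf(", convergence = %.3f", x$convergence_ratio))
  if (!is.na(x$effective))
    cat(sprintf(", %s", if (x$effective) "effective" else "not effective"))
  cat("\n")
  invisible(x)
}

#' @export
summary.rffg <- function(object, ...) {
  print(object)
  rng <- range(object$grid)
  cat(sprintf("  range [%.4g, %.4g]; +cells %d, -cells %d (of %d)\n",
              rng[1], rng[2], sum(object$grid > 0), sum(object$grid < 0),
              length(object$grid)))
  invisible(object)
}

#' @export
coef.rffg <- function(object, ...) object$grid

#' Plot a kernel as a signed-colormap image
#'
#' Red marks figure-preferring (positive) cells, blue ground-preferring
#' (negative) cells; color is symmetric about zero.
#'
#' @param x An \code{rffg}.
#' @param ... Passed to \code{\link[graphics]{image}}.
#' @export
plot.rffg <- function(x, ...) {
  g <- x$grid
  m <- max(abs(g), 1e-12)
  pal <- grDevices::colorRampPalette(c("#2166AC", "white", "#B2182B"))(101)
  graphics::image(seq_len(ncol(g)) - 1, seq_len(nrow(g)) - 1,
                  t(g[nrow(g):1, ]), zlim = c(-m, m), col = pal,
                  xlab = "col", ylab = "row", asp = 1,
                  main = sprintf("%s kernel", x$estimator), ...)
  invisible(x)
}
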