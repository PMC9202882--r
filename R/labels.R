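# Data model for figure-ground label stimuli and spike-count tables.
#
# Conventions used throughout the package:
#  * label grids are G x G numeric matrices with entries in {+1, -1, 0}:
#    +1 figure, -1 ground, 0 masked (excluded from extent computations);
#  * cell indices are 0-based (row, col) in documentation and metadata; the
#    patch center is cell ((G-1)/2, (G-1)/2), i.e. (12, 12) for G = 25;
#  * continuous positions are measured in cell units from the grid center.

#' Construct a figure-ground label
#'
#' A figure-ground (FG) label tags every cell of a small square grid as
#' figure (+1), ground (-1) or masked (0). For non-dot labels the boundary
#' between the figure and ground regions passes through the patch center.
#'
#' @param grid Square numeric matrix with values in \{+1, -1, 0\}.
#' @param stimulus_id Character scalar identifying the stimulus.
#' @param stimulus_class One of \code{"filled"}, \code{"natural"},
#'   \code{"dot"}, \code{"synthetic"}.
#' @param mirror_partner,contrast_partner Optional ids of the
#'   figure/ground-swapped mirror stimulus and of the opposite-contrast
#'   stimulus sharing the same label.
#' @param check Validate invariants (default \code{TRUE}). Dot labels and
#'   labels flagged \code{translated} are exempt from the
#'   boundary-through-center requirement.
#' @param translated Logical; translated copies waive the center-boundary
#'   invariant.
#' @return An object of class \code{"fg_label"}.
#' @export
fg_label <- function(grid, stimulus_id, stimulus_class = "synthetic",
                     mirror_partner = NULL, contrast_partner = NULL,
                     check = TRUE, translated = FALSE) {
  grid <- as.matrix(grid)
  obj <- structure(
    list(grid = grid, stimulus_id = as.character(stimulus_id),
         stimulus_class = stimulus_class,
         mirror_partner = mirror_partner,
         contrast_partner = contrast_partner,
         translated = isTRUE(translated)),
    class = "fg_label")
  if (check) validate_fg_label(obj)
  obj
}

#' Validate a figure-ground label
#'
#' Checks the value-set invariant (every cell in \{+1, -1, 0\}), the
#' presence of both figure and ground cells for non-dot labels, and the
#' boundary-through-center invariant (the center cell has a 4-neighbor of
#' opposite sign) for non-dot, non-translated labels.
#'
#' @param x An \code{fg_label}.
#' @return \code{x}, invisibly; signals an error on violation.
#' @export
validate_fg_label <- function(x) {
  g <- x$grid
  if (!is.matrix(g) || nrow(g) != ncol(g))
    stop("fg_label grid must be a square matrix", call. = FALSE)
  bad <- which(!(g %in% c(-1, 0, 1)))
  if (length(bad)) {
    rc <- arrayInd(bad, dim(g)) - 1L
    stop(sprintf("fg_label '%s': cells outside {+1,-1,0} at (row,col): %s",
                 x$stimulus_id,
                 paste(sprintf("(%d,%d)", rc[, 1], rc[, 2]), collapse = " ")),
         call. = FALSE)
  }
  if (!identical(x$stimulus_class, "dot")) {
    if (!any(g == 1) || !any(g == -1))
      stop(sprintf("fg_label '%s': non-dot label needs at least one +1 and one -1 cell",
                   x$stimulus_id), call. = FALSE)
    if (!isTRUE(x$translated)) {
      G <- nrow(g)
      cc <- as.integer(floor((G - 1) / 2)) + 1L
      ctr <- g[cc, cc]
      nb <- c(if (cc > 1L) g[cc - 1L, cc], if (cc < G) g[cc + 1L, cc],
              if (cc > 1L) g[cc, cc - 1L], if (cc < G) g[cc, cc + 1L])
      if (ctr != 0 && !any(nb == -ctr))
        stop(sprintf("fg_label '%s': boundary does not pass through the grid center",
                     x$stimulus_id), call. = FALSE)
    }
  }
  invisible(x)
}

#' @export
print.fg_label <- function(x, ...) {
  cat(sprintf("<fg_label '%s'> %dx%d %s (+1: %d, -1: %d, 0: %d)\n",
              x$stimulus_id, nrow(x$grid), ncol(x$grid), x$stimulus_class,
              sum(x$grid == 1), sum(x$grid == -1), sum(x$grid == 0)))
  invisible(x)
}

#' Construct a stimulus set
#'
#' Bundles an ordered collection of \code{\link{fg_label}}s with the
#' ensemble-mean label used for bias compensation in the spike-triggered
#' average.
#'
#' @param labels List of \code{fg_label} objects with a common grid size.
#' @return An object of class \code{"fg_stimset"} with elements
#'   \code{labels} (named list), \code{N} (number of labels),
#'   \code{grid_size} and \code{mean_label} (element-wise mean grid).
#' @export
stimulus_set <- function(labels) {
  if (!length(labels)) stop("stimulus_set: empty label list", call. = FALSE)
  ids <- vapply(labels, function(l) l$stimulus_id, character(1))
  if (anyDuplicated(ids))
    stop("stimulus_set: duplicated stimulus ids", call. = FALSE)
  G <- nrow(labels[[1]]$grid)
  ok <- vapply(labels, function(l) all(dim(l$grid) == c(G, G)), logical(1))
  if (!all(ok)) stop("stimulus_set: inconsistent grid sizes", call. = FALSE)
  names(labels) <- ids
  structure(list(labels = labels, N = length(labels), grid_size = G,
                 mean_label = Reduce(`+`, lapply(labels, `[[`, "grid")) /
                   length(labels)),
            class = "fg_stimset")
}

#' @export
print.fg_stimset <- function(x, ...) {
  cat(sprintf("<fg_stimset> N = %d labels on a %dx%d grid (classes: %s)\n",
              x$N, x$grid_size, x$grid_size,
              paste(unique(vapply(x$labels, `[[`, character(1),
                                  "stimulus_class")), collapse = ", ")))
  invisible(x)
}

#' Ensemble-mean label of a stimulus set
#'
#' The element-wise arithmetic mean of all label grids. Subtracting it from
#' the spike-weighted average compensates for the non-uniform distribution
#' of figure and ground over the ensemble; for any set closed under
#' figure/ground swap it is exactly zero.
#'
#' @param labels An \code{fg_stimset}.
#' @return A G x G numeric matrix with values in [-1, +1].
#' @export
ensemble_mean_label <- function(labels) {
  stopifnot(inherits(labels, "fg_stimset"))
  if (labels$N < 1) stop("empty stimulus set", call. = FALSE)
  labels$mean_label
}

#' Stack a stimulus set's grids as a matrix
#'
#' @param labels An \code{fg_stimset}.
#' @return An N x G^2 matrix; row i is label i's grid flattened column-major.
#' @export
label_matrix <- function(labels) {
  stopifnot(inherits(labels, "fg_stimset"))
  t(vapply(labels$labels, function(l) as.vector(l$grid),
           numeric(labels$grid_size^2)))
}

#' Construct a spike-count table
#'
#' Per-stimulus, per-trial spike counts in the stimulus window (40-200 ms
#' after onset) and the pre-stimulus window (100-0 ms before onset).
#'
#' @param stimulus_id,trial,pre_count,stim_count Equal-length vectors.
#' @return A data frame of class \code{"fg_spikes"}.
#' @export
spike_table <- function(stimulus_id, trial, pre_count, stim_count) {
  df <- data.frame(stimulus_id = as.character(stimulus_id),
                   trial = as.integer(trial),
                   pre_count = as.integer(pre_count),
                   stim_count = as.integer(stim_count),
                   stringsAsFactors = FALSE)
  if (any(df$pre_count < 0) || any(df$stim_count < 0))
    stop("spike_table: counts must be non-negative", call. = FALSE)
  class(df) <- c("fg_spikes", "data.frame")
  df
}

#' Per-stimulus total spike counts
#'
#' The per-stimulus drive used by the estimators: the sum of
#' stimulus-window counts over trials.
#'
#' @param spikes An \code{fg_spikes} table.
#' @param ids Optional stimulus ids fixing the order (default: order of
#'   first appearance).
#' @return Named numeric vector of totals.
#' @export
spike_totals <- function(spikes, ids = NULL) {
  tot <- tapply(spikes$stim_count, spikes$stimulus_id, sum)
  if (is.null(ids)) ids <- unique(spikes$stimulus_id)
  missing <- setdiff(ids, names(tot))
  if (length(missing))
    stop("spike_totals: no rows for stimuli: ",
         paste(missing, collapse = ", "), call. = FALSE)
  out <- as.numeric(tot[ids])
  names(out) <- ids
  out
}

#' Pool opposite-contrast stimulus pairs
#'
#' Filled stimuli come in pairs of opposite contrast polarity sharing one
#' FG label; the pair is collapsed to a single label whose spike counts are
#' the trial-wise sums of the pair's counts. Unpaired labels pass through
#' unchanged.
#'
#' @param labels An \code{fg_stimset} whose labels may carry
#'   \code{contrast_partner} links (symmetric, acyclic).
#' @param spikes Matching \code{fg_spikes} table.
#' @return List with elements \code{labels} (pooled \code{fg_stimset}) and
#'   \code{spikes} (pooled \code{fg_spikes}).
#' @export
pool_contrast_pairs <- function(labels, spikes) {
  stopifnot(inherits(labels, "fg_stimset"))
  ids <- names(labels$labels)
  partner <- vapply(labels$labels, function(l)
    if (is.null(l$contrast_partner)) NA_character_ else l$contrast_partner,
    character(1))
  dangling <- !is.na(partner) & !(partner %in% ids)
  if (any(dangling))
    stop("pool_contrast_pairs: dangling contrast_partner reference(s): ",
         paste(partner[dangling], collapse = ", "), call. = FALSE)
  asym <- !is.na(partner) & (is.na(partner[partner]) | partner[partner] != ids)
  if (any(asym))
    stop("pool_contrast_pairs: contrast_partner links are not symmetric",
         call. = FALSE)

  keep <- character(0)
  drop_of <- character(0)   # names: dropped id -> kept id
  for (id in ids) {
    p <- partner[[id]]
    if (is.na(p)) keep <- c(keep, id)
    else if (!(p %in% keep) && !(id %in% names(drop_of))) {
      keep <- c(keep, id)
      drop_of[p] <- id
    }
  }
  new_labels <- lapply(keep, function(id) {
    l <- labels$labels[[id]]
    l$contrast_partner <- NULL
    l
  })
  sp <- spikes
  remap <- sp$stimulus_id
  in_drop <- remap %in% names(drop_of)
  remap[in_drop] <- drop_of[remap[in_drop]]
  agg <- stats::aggregate(cbind(pre_count, stim_count) ~ stimulus_id + trial,
                          data = transform(sp, stimulus_id = remap), FUN = sum)
  list(labels = stimulus_set(new_labels),
       spikes = spike_table(agg$stimulus_id, agg$trial,
                            agg$pre_count, agg$stim_count))
}
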