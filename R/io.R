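# Plain-text / PNG I/O: label masks, spike-count tables, kernel matrices.
# Formats: masks as 8-bit grayscale PNG (0 = ground, 255 = figure,
# 128 = masked); spike tables as CSV; kernels as tab-delimited matrices with
# a JSON sidecar carrying provenance and significance annotations.

#' Load a directory of label masks into a stimulus set
#'
#' Reads 8-bit PNG masks (0 = ground, 255 = figure, 128 = masked) listed in
#' a \code{metadata.json} table and resamples each to \code{grid_size} by
#' majority vote per cell (ties to figure).
#'
#' @param path Directory containing mask PNGs and \code{metadata.json}; the
#'   metadata is an array of objects with fields \code{file},
#'   \code{stimulus_id}, \code{stimulus_class} and optional
#'   \code{mirror_partner}, \code{contrast_partner}, \code{translated}.
#' @param grid_size Target grid size G.
#' @return An \code{\link{stimulus_set}}.
#' @export
load_labels <- function(path, grid_size) {
  meta_path <- file.path(path, "metadata.json")
  if (!file.exists(meta_path))
    stop("load_labels: missing metadata.json in ", path, call. = FALSE)
  meta <- jsonlite::fromJSON(meta_path, simplifyDataFrame = TRUE)
  req <- c("file", "stimulus_id", "stimulus_class")
  if (!all(req %in% names(meta)))
    stop("load_labels: metadata.json lacks required fields: ",
         paste(setdiff(req, names(meta)), collapse = ", "), call. = FALSE)
  labels <- lapply(seq_len(nrow(meta)), function(i) {
    img <- png::readPNG(file.path(path, meta$file[i]))
    if (length(dim(img)) == 3) img <- img[, , 1]
    lev <- round(img * 255)
    tri <- matrix(0, nrow(lev), ncol(lev))
    tri[lev >= 192] <- 1
    tri[lev < 64] <- -1
    fg_label(downsample_majority(tri, grid_size),
             stimulus_id = meta$stimulus_id[i],
             stimulus_class = meta$stimulus_class[i],
             mirror_partner = opt_field(meta, "mirror_partner", i),
             contrast_partner = opt_field(meta, "contrast_partner", i),
             translated = isTRUE(opt_field(meta, "translated", i)))
  })
  stimulus_set(labels)
}

opt_field <- function(meta, field, i) {
  if (!field %in% names(meta)) return(NULL)
  v <- meta[[field]][i]
  if (is.na(v) || identical(v, "")) NULL else v
}

#' Majority-vote downsampling of a tri-valued mask
#'
#' Partitions the source into \code{grid_size}^2 near-equal rectangular
#' blocks and assigns each target cell the most frequent source value,
#' breaking ties toward figure (+1), then ground (-1).
#'
#' @param m Matrix with values in \{+1, -1, 0\}.
#' @param grid_size Target size.
#' @return \code{grid_size} x \code{grid_size} matrix.
#' @export
downsample_majority <- function(m, grid_size) {
  rb <- block_index(nrow(m), grid_size)
  cb <- block_index(ncol(m), grid_size)
  out <- matrix(0, grid_size, grid_size)
  for (i in seq_len(grid_size)) for (j in seq_len(grid_size)) {
    v <- m[rb == i, cb == j]
    n_fig <- sum(v == 1); n_gnd <- sum(v == -1); n_msk <- sum(v == 0)
    out[i, j] <- if (n_fig >= max(n_gnd, n_msk)) 1
                 else if (n_gnd >= n_msk) -1 else 0
  }
  out
}

block_index <- function(n, k) {
  if (n < k) stop("downsample_majority: source smaller than target grid",
                  call. = FALSE)
  as.integer(cut(seq_len(n), breaks = round(seq(0, n, length.out = k + 1)),
                 labels = FALSE))
}

#' Write a stimulus set as PNG masks plus metadata
#'
#' Inverse of \code{\link{load_labels}} at equal resolution: grids are
#' written 1:1 as 8-bit PNGs (255/0/128 for +1/-1/0).
#'
#' @param labels An \code{fg_stimset}.
#' @param path Output directory (created if absent).
#' @return \code{path}, invisibly.
#' @export
write_labels <- function(labels, path) {
  stopifnot(inherits(labels, "fg_stimset"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- lapply(labels$labels, function(l) {
    f <- paste0(l$stimulus_id, ".png")
    img <- matrix(0.5, nrow(l$grid), ncol(l$grid))
    img[l$grid == 1] <- 1
    img[l$grid == -1] <- 0
    png::writePNG(img, file.path(path, f))
    list(file = f, stimulus_id = l$stimulus_id,
         stimulus_class = l$stimulus_class,
         mirror_partner = l$mirror_partner,
         contrast_partner = l$contrast_partner,
         translated = l$translated)
  })
  jsonlite::write_json(unname(meta), file.path(path, "metadata.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Write an estimated kernel to disk
#'
#' Writes the kernel grid as a tab-delimited numeric matrix at full double
#' precision plus a JSON sidecar with estimator provenance, magnitude,
#' permutation p-value and convergence annotations.
#'
#' @param kernel An \code{rffg} object (see \code{\link{rffg}}).
#' @param path Output path for the TSV; the sidecar is written alongside as
#'   \code{<path>.json}.
#' @return \code{path}, invisibly.
#' @export
write_kernel <- function(kernel, path) {
  stopifnot(inherits(kernel, "rffg"))
  utils::write.table(format(kernel$grid, digits = 17, scientific = TRUE,
                            trim = TRUE),
                     path, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  side <- kernel[setdiff(names(kernel), "grid")]
  side <- side[!vapply(side, is.null, logical(1))]
  side <- lapply(side, function(v) if (is.matrix(v)) as.vector(v) else v)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a kernel written by \code{write_kernel}
#'
#' @param path Path to the TSV matrix; \code{<path>.json} must exist.
#' @return An \code{rffg} object.
#' @export
read_kernel <- function(path) {
  grid <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(grid) <- NULL
  side <- jsonlite::fromJSON(paste0(path, ".json"))
  side$magnitude <- NULL   # recomputed from the grid
  side$effective <- NULL   # recomputed from p_perm and convergence_ratio
  do.call(rffg, c(list(grid = grid), side))
}

#' Read / write spike-count tables as CSV
#'
#' CSV columns: \code{stimulus_id}, \code{trial}, \code{pre_count},
#' \code{stim_count}.
#'
#' @param path File path.
#' @return \code{read_spike_table}: an \code{fg_spikes} table.
#' @export
read_spike_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  spike_table(df$stimulus_id, df$trial, df$pre_count, df$stim_count)
}

#' @rdname read_spike_table
#' @param spikes An \code{fg_spikes} table.
#' @export
write_spike_table <- function(spikes, path) {
  utils::write.csv(as.data.frame(spikes), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
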