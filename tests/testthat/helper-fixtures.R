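# Shared builders for the test suite. Everything is generated in code;
# small grids keep most tests fast, with full 25-cell grids reserved for
# the checks whose substance depends on that resolution.

# A left-half-figure / right-half-ground label on a G-cell grid.
left_half_label <- function(G = 9, id = "left") {
  g <- matrix(-1, G, G)
  g[, seq_len(ceiling(G / 2))] <- 1
  fg_label(g, id)
}

# Duplicate every label of a set as an opposite-contrast partner pair.
with_contrast_partners <- function(set) {
  out <- list()
  for (l in set$labels) {
    a <- l
    b <- l
    a$contrast_partner <- paste0(l$stimulus_id, "_c2")
    b$stimulus_id <- paste0(l$stimulus_id, "_c2")
    b$contrast_partner <- l$stimulus_id
    b$mirror_partner <- NULL
    out[[a$stimulus_id]] <- a
    out[[b$stimulus_id]] <- b
  }
  stimulus_set(out)
}

# Spike table with a fixed count per (stimulus, trial) from a named vector
# of per-stimulus per-trial counts.
counts_table <- function(ids, per_trial, n_trials = 10, pre = 0) {
  spike_table(stimulus_id = rep(ids, each = n_trials),
              trial = rep(seq_len(n_trials), times = length(ids)),
              pre_count = pre,
              stim_count = rep(per_trial, each = n_trials))
}

# Closed-form ideal-kernel oracle on the uniform half-plane ensemble:
# the expected value at a cell whose offset from the grid center makes an
# angle theta with the CRF-center offset is 1 - 2*theta/pi (theta in
# [0, pi/2] after folding; equivalently 1 - 2*theta/pi for theta in
# [0, pi] with sign).
ideal_halfplane_oracle <- function(G, crf_center) {
  ctr <- (G - 1) / 2
  p <- crf_center - ctr
  out <- matrix(NA_real_, G, G)
  for (i in seq_len(G)) for (j in seq_len(G)) {
    x <- c(i - 1 - ctr, j - 1 - ctr)
    if (sum(x^2) == 0 || sum(p^2) == 0) { out[i, j] <- NA; next }
    ct <- sum(x * p) / sqrt(sum(x^2) * sum(p^2))
    theta <- acos(pmin(pmax(ct, -1), 1))
    out[i, j] <- 1 - 2 * theta / pi
  }
  out
}

# Smooth compact center-surround test kernel (for warp round trips).
smooth_blob <- function(G, ctr, s) {
  r <- matrix(rep(seq_len(G) - 1, times = G), G, G)
  c_ <- matrix(rep(seq_len(G) - 1, each = G), G, G)
  exp(-((r - ctr)^2 + (c_ - ctr)^2) / (2 * s^2)) -
    0.6 * exp(-((r - ctr - 3)^2 + (c_ - ctr)^2) / (2 * s^2))
}
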