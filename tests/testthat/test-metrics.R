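test_that("cosine similarity behaves as an angle on kernel space", {
  set.seed(30)
  k <- matrix(rnorm(25), 5, 5)
  expect_equal(cosine_similarity(k, k), 1)
  expect_equal(cosine_similarity(k, -k), -1)
  expect_equal(cosine_similarity(k, 3.7 * k), 1)
  k2 <- matrix(rnorm(25), 5, 5)
  expect_equal(cosine_similarity(k, k2), cosine_similarity(k2, k))
  # orthogonal half-plane kernels: left/right vs top/bottom
  hp <- gen_halfplane_labels(2, 25)
  lr <- hp$labels[["hp001a"]]$grid
  tb <- hp$labels[["hp002a"]]$grid
  # exactly 1/625 from the figure tie-break on the center row/column
  expect_lt(abs(cosine_similarity(lr, tb)), 0.01)
  expect_error(cosine_similarity(k, matrix(0, 5, 5)), "zero-norm")
})

test_that("PR ratio measures the preferred-sign share of the support", {
  expect_equal(pr_ratio(matrix(1, 5, 5), "figure"), 1)
  anti <- cbind(matrix(1, 6, 3), matrix(-1, 6, 3))
  expect_equal(pr_ratio(anti, "figure"), 0.5)
  expect_equal(pr_ratio(anti, "ground"), 0.5)
  expect_equal(pr_ratio(2 * anti, "figure"), pr_ratio(anti, "figure"))
  # sub-threshold cells drop out of the support
  g <- anti; g[, 1] <- 0.01
  expect_equal(pr_ratio(g, "figure"), 12 / 30)
  expect_error(pr_ratio(matrix(0, 3, 3), "figure"), "zero")
})

test_that("overlap ratio matches a brute-force cell enumeration", {
  cf <- crf(c(12, 12), 4, 2.5, 0.6)
  # preferred region: left half-plane kernel
  g <- cbind(matrix(1, 25, 13), matrix(-1, 25, 12))
  got <- overlap_ratio(cf, g, "figure")
  inside <- 0; unions <- 0
  for (i in 0:24) for (j in 0:24) {
    dc <- j - 12; dr <- i - 12
    u <- cos(0.6) * dc + sin(0.6) * dr
    v <- -sin(0.6) * dc + cos(0.6) * dr
    in_ell <- (u / 4)^2 + (v / 2.5)^2 <= 1
    in_pref <- g[i + 1, j + 1] > 0
    inside <- inside + (in_ell && in_pref)
    unions <- unions + (in_ell || in_pref)
  }
  expect_equal(got, inside / unions)
  # exact coincidence and disjointness
  ell <- fgfield:::rasterize_crf_ellipse(cf, 25)
  gg <- matrix(-1, 25, 25); gg[ell] <- 1
  expect_equal(overlap_ratio(cf, gg, "figure"), 1)
  expect_equal(overlap_ratio(cf, gg, "ground"), 0)
})

test_that("rotation alignment sends the preferred center of gravity to the reference side", {
  hp <- gen_halfplane_labels(8, 25)
  ik <- ideal_rffg(hp, crf(c(12, 6), 3, 3), "figure")
  ra <- rotate_align(ik, "figure")
  g <- ra$grid
  supp <- abs(g) > 0.05 * max(abs(g))
  pref <- supp & g > 0
  idx <- which(pref, arr.ind = TRUE) - 1
  w <- abs(g)[pref]
  cog <- c(sum(w * idx[, 1]), sum(w * idx[, 2])) / sum(w) - 12
  expect_equal(cos(atan2(cog[1], cog[2]) - pi), 1, tolerance = 1e-3)
  # a kernel whose center of gravity already sits exactly left is
  # returned unchanged (zero rotation, exact resampling)
  blk <- cbind(matrix(1, 25, 12), matrix(-1, 25, 13))
  expect_lt(max(abs(rotate_align(blk, "figure")$grid - blk)), 1e-9)
  # realigning an aligned kernel applies only a residual rotation; the
  # sharp boundary makes per-cell interpolation error the wrong yardstick
  again <- rotate_align(ra, "figure")
  d <- attr(again, "angle") %% (2 * pi)
  expect_lt(min(d, 2 * pi - d), 0.02)
  expect_gt(cosine_similarity(again, ra), 0.995)
  # a 90-degree-rotated copy aligns onto the same kernel
  k90 <- rffg(t(ik$grid)[, 25:1])
  expect_gt(cosine_similarity(rotate_align(k90, "figure"), ra), 0.995)
  # degenerate center of gravity
  iso <- matrix(1, 9, 9)
  expect_error(rotate_align(iso, "figure"), "undefined")
})

test_that("CRF scaling is the identity at the target and inverts on smooth kernels", {
  G <- 49
  k <- smooth_blob(G, 24, 6)
  cf <- crf(c(24, 24), 4, 4)
  same <- scale_by_crf(k, cf, 4)
  expect_lt(max(abs(same$grid - k)), 1e-12)
  up <- scale_by_crf(k, cf, 5)
  back <- scale_by_crf(up, crf(c(24, 24), 5, 5), 4)
  expect_lt(max(abs(back$grid - k)) / max(abs(k)), 0.02)
  # non-positive CRF extents are rejected at construction
  expect_error(crf(c(24, 24), 0, 0), "positive")
})

test_that("population averaging aligns, normalizes and degrades gracefully", {
  hp <- gen_halfplane_labels(8, 25)
  ik <- ideal_rffg(hp, crf(c(12, 6), 3, 3), "figure")
  pm <- population_mean(list(ik, ik), "crf_centered",
                        crfs = list(crf(c(12, 6), 3, 3),
                                    crf(c(12, 6), 3, 3)))
  expect_equal(attr(pm, "n_used"), 2L)
  expect_equal(pm$grid, fgfield:::center_on_crf(ik$grid / max(abs(ik$grid)),
                                                crf(c(12, 6), 3, 3)),
               tolerance = 1e-12)
  # kernel plus its negation cancel
  pm0 <- population_mean(list(ik$grid, -ik$grid), "crf_centered",
                         crfs = list(crf(c(12, 6), 3, 3),
                                     crf(c(12, 6), 3, 3)))
  expect_lt(max(abs(pm0$grid)), 1e-12)
  # ideal figure cells at scattered CRF centers: centered mean shows a
  # central positive lobe with a negative surround
  centers <- list(c(12, 5), c(6, 12), c(18, 16), c(12, 19), c(8, 7))
  ks <- lapply(centers, function(ct) ideal_rffg(hp, crf(ct, 3, 3), "figure"))
  cfs <- lapply(centers, function(ct) crf(ct, 3, 3))
  pmc <- population_mean(ks, "crf_centered", crfs = cfs)
  expect_gt(pmc$grid[13, 13], 0.5)
  border <- c(pmc$grid[2, ], pmc$grid[24, ], pmc$grid[, 2], pmc$grid[, 24])
  expect_lt(mean(border), 0)
  # zero kernels are excluded with a warning; all excluded errors
  expect_warning(
    pz <- population_mean(list(ik$grid, matrix(0, 25, 25)), "crf_centered",
                          crfs = cfs[1:2]), "excluded")
  expect_equal(attr(pz, "n_used"), 1L)
  expect_error(suppressWarnings(
    population_mean(list(matrix(0, 25, 25)), "crf_centered", crfs = cfs[1])),
    "all kernels excluded")
})
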