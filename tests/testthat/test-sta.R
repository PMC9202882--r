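test_that("equal responses give an exactly zero kernel (flat null)", {
  hp <- gen_halfplane_labels(6, 15)
  sp <- counts_table(names(hp$labels), 7, n_trials = 4)
  k <- rffg_sta(hp, sp, n_perm = 0)
  expect_identical(max(abs(k$grid)), 0)
  expect_identical(k$magnitude, 0)
})

test_that("the STA is invariant to positive scaling of all counts", {
  hp <- gen_halfplane_labels(6, 15)
  sp <- counts_table(names(hp$labels), seq_len(hp$N), n_trials = 2)
  sp2 <- sp; sp2$stim_count <- 7L * sp2$stim_count
  expect_equal(rffg_sta(hp, sp, n_perm = 0)$grid,
               rffg_sta(hp, sp2, n_perm = 0)$grid, tolerance = 1e-12)
})

test_that("single-support spiking returns that label minus the ensemble mean", {
  hp <- gen_halfplane_labels(4, 9)
  per <- rep(0, hp$N); per[3] <- 5
  sp <- counts_table(names(hp$labels), per, n_trials = 2)
  k <- rffg_sta(hp, sp, n_perm = 0)
  expect_equal(k$grid, hp$labels[[3]]$grid - hp$mean_label)
  # all-zero spikes are a domain error
  expect_error(rffg_sta(hp, counts_table(names(hp$labels), 0), n_perm = 0),
               "zero")
})

test_that("the ideal-cell STA matches the closed-form half-plane oracle", {
  G <- 25
  hp <- gen_halfplane_labels(105, G)
  cf <- crf(c(12, 6), 3, 3)
  sp <- simulate_responses(virtual_neuron("ideal_fg", crf = cf), hp,
                           n_trials = 10, seed = 1)
  k <- rffg_sta(hp, sp, n_perm = 0)
  # equivalently the mean of the selected labels (ensemble mean is zero)
  ik <- ideal_rffg(hp, cf, "figure")
  expect_equal(k$grid, ik$grid, tolerance = 1e-12)
  oracle <- ideal_halfplane_oracle(G, c(12, 6))
  use <- !is.na(oracle) & (abs(oracle) < 0.999)
  # away from degenerate angles the pixelated kernel tracks 1 - 2*theta/pi
  expect_lt(mean(abs(k$grid[use] - oracle[use])), 0.03)
  expect_gt(stats::cor(as.vector(k$grid[use]), as.vector(oracle[use])),
            0.999)
  # STA values stay within [-1, 1]
  expect_true(all(abs(k$grid) <= 1))
})

test_that("figure- and ground-preferring ideal kernels are exact negatives", {
  hp <- gen_halfplane_labels(20, 15)
  cf <- crf(c(7, 3), 2, 2)
  f <- ideal_rffg(hp, cf, "figure")
  g <- ideal_rffg(hp, cf, "ground")
  expect_equal(f$grid, -g$grid, tolerance = 1e-12)
  expect_equal(f$preference, "figure")
})

test_that("permutation significance separates FG cells from flat cells", {
  hp <- gen_halfplane_labels(30, 15)
  cf <- crf(c(7, 3), 2, 2)
  sp <- simulate_responses(virtual_neuron("ideal_fg", crf = cf), hp,
                           n_trials = 10, seed = 2)
  expect_lt(sta_permutation_test(hp, sp, n_perm = 200, seed = 3), 0.05)
  # degenerate equal counts: p = 1 by construction
  flat <- counts_table(names(hp$labels), 4, n_trials = 2)
  expect_equal(sta_permutation_test(hp, flat, n_perm = 50, seed = 4), 1)
  # add-one estimator bounds
  one <- sta_permutation_test(hp, sp, n_perm = 1, seed = 5)
  expect_true(one %in% c(0.5, 1))
  expect_identical(sta_permutation_test(hp, sp, n_perm = 100, seed = 6),
                   sta_permutation_test(hp, sp, n_perm = 100, seed = 6))
})

test_that("the convergence curve ends at the full-set magnitude and decays for noise cells", {
  hp <- gen_halfplane_labels(30, 15)
  sp <- simulate_responses(
    virtual_neuron("non_fg", constant = 5, noise = "poisson"),
    hp, n_trials = 10, seed = 7)
  cv <- convergence_curve(hp, sp, step = 10, reps = 20, seed = 8)
  full <- rffg_sta(hp, sp, n_perm = 0)$magnitude
  expect_equal(cv$magnitude[nrow(cv)], full, tolerance = 1e-12)
  # sampling noise shrinks as subsets grow: small-n magnitude dominates
  expect_gt(cv$magnitude[1], 2 * cv$magnitude[nrow(cv)])
  expect_identical(convergence_curve(hp, sp, 10, 5, seed = 9),
                   convergence_curve(hp, sp, 10, 5, seed = 9))
})

test_that("the saturating convergence model recovers its own curves", {
  x <- seq(20, 200, by = 20)
  a <- 10; b <- 0.8; cc <- 60; d <- 1.2
  y <- a * (1 - b * exp(-(x / cc)^d))
  fit <- fit_convergence(
    structure(data.frame(size = x, magnitude = y),
              class = c("fg_convcurve", "data.frame"), N = 200))
  expect_equal(unname(fit$par[["a"]]), a, tolerance = 0.05)
  expect_equal(fit$fitted, y, tolerance = 0.01)
  expect_equal(fit$ratio, y[length(y)] / a, tolerance = 0.02)
  # flat curves saturate: a ~ level, ratio ~ 1
  flat <- structure(data.frame(size = x, magnitude = 5),
                    class = c("fg_convcurve", "data.frame"), N = 200)
  ff <- fit_convergence(flat)
  expect_equal(unname(ff$par[["a"]]), 5, tolerance = 0.01)
  expect_equal(ff$ratio, 1, tolerance = 0.01)
  expect_error(fit_convergence(flat[1:4, ]), "6")
})

test_that("effectiveness requires significance and convergence jointly", {
  k1 <- rffg(matrix(0.1, 3, 3), p_perm = 0.01, convergence_ratio = 0.95)
  k2 <- rffg(matrix(0.1, 3, 3), p_perm = 0.2, convergence_ratio = 0.95)
  k3 <- rffg(matrix(0.1, 3, 3), p_perm = 0.01, convergence_ratio = 0.5)
  expect_true(k1$effective)
  expect_false(k2$effective)
  expect_false(k3$effective)
})

test_that("dot probing identifies rectified-linear kernels up to scale", {
  G <- 9
  k <- make_dog_kernel(center = c(4, 4), orientation = 0.5,
                       sigma_center = 1.2, sigma_surround = 2,
                       grid_size = G)
  dots <- gen_dot_stimuli(G)
  sp <- simulate_responses(
    virtual_neuron("rectified_linear", kernel = k, gain = 1e4),
    dots, n_trials = 1, seed = 1)
  est <- rffg_sta(dots, sp, n_perm = 0)
  expect_gt(cosine_similarity(est, k), 0.9999)
})
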