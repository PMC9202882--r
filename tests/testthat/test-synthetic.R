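test_that("half-plane ensembles have the designed structure", {
  hp <- gen_halfplane_labels(2, 25)
  expect_equal(hp$N, 4)
  # orientation 0: left/right split at the center column
  g <- hp$labels[["hp001a"]]$grid
  expect_true(all(g[, 13:25] == 1) && all(g[, 1:12] == -1))
  # mirror partners are exact negations, so the mean cancels exactly
  expect_identical(hp$labels[["hp001b"]]$grid, -g)
  expect_equal(max(abs(hp$mean_label)), 0)
  big <- gen_halfplane_labels(105, 25)
  expect_equal(big$N, 210)
  expect_equal(max(abs(big$mean_label)), 0)
  expect_error(gen_halfplane_labels(1, 25), "n_orientations")
})

test_that("curved ensembles are seeded, center-crossing and swap-closed", {
  a <- gen_curved_labels(10, 15, curvature_sd = 2, seed = 5)
  b <- gen_curved_labels(10, 15, curvature_sd = 2, seed = 5)
  expect_identical(label_matrix(a), label_matrix(b))
  expect_equal(a$N, 20)
  expect_equal(max(abs(a$mean_label)), 0)
  # center-boundary invariant holds for every label (validator re-run)
  for (l in a$labels) expect_silent(validate_fg_label(l))
  # zero curvature degenerates to straight boundaries: every row and
  # column then changes sign at most once
  s0 <- gen_curved_labels(8, 15, curvature_sd = 0, seed = 9)
  max_changes <- function(g)
    max(c(apply(g, 1, function(v) sum(diff(v) != 0)),
          apply(g, 2, function(v) sum(diff(v) != 0))))
  for (l in s0$labels) expect_lte(max_changes(l$grid), 1)
})

test_that("dot ensembles are exhaustive, paired and zero-mean", {
  d2 <- gen_dot_stimuli(2)
  expect_equal(d2$N, 8)
  expect_equal(unname(sort(vapply(d2$labels, function(l) sum(l$grid),
                                  numeric(1)))),
               rep(c(-1, 1), each = 4))
  d25 <- gen_dot_stimuli(25)
  expect_equal(d25$N, 1250)
  expect_equal(max(abs(d25$mean_label)), 0)
})

test_that("translation shifts boundaries and fills edges from the nearer side", {
  hp <- gen_halfplane_labels(2, 9)
  expect_identical(gen_translated_labels(hp, list(c(0, 0))), hp)
  tr <- gen_translated_labels(hp, list(c(2, 0)))
  g0 <- hp$labels[["hp001a"]]$grid      # right half figure
  g1 <- tr$labels[["hp001a_t01"]]$grid
  expect_identical(g1[, 3:9], g0[, 1:7])       # shifted content
  expect_true(all(g1[, 1:2] == g0[, 1]))       # edge replication
  expect_true(tr$labels[["hp001a_t01"]]$translated)
  expect_error(gen_translated_labels(hp, list(c(9, 0))), "shift")
})

test_that("translated ensembles keep closely similar magnitude spectra", {
  hp <- gen_halfplane_labels(12, 25)
  spec_mean <- function(ss)
    Reduce(`+`, lapply(ss$labels, function(l) abs(stats::fft(l$grid)))) / ss$N
  s0 <- spec_mean(hp)
  s1 <- spec_mean(gen_translated_labels(hp, list(c(2, 0))))
  expect_gt(stats::cor(as.vector(s0), as.vector(s1)), 0.95)
})

test_that("DoG kernels are odd-symmetric, unit-norm and side-selective", {
  k <- make_dog_kernel(center = c(12, 12), orientation = 0.7,
                       sigma_center = 2, sigma_surround = 3.5,
                       grid_size = 25)
  expect_equal(sum(k^2), 1, tolerance = 1e-12)
  # reflecting the grid through the center negates the kernel exactly
  expect_equal(k, -k[25:1, 25:1], tolerance = 1e-12)
  # aligned half-plane drives the positive lobe
  hp <- gen_halfplane_labels(2, 25)
  kx <- make_dog_kernel(center = c(12, 12), orientation = 0,
                        sigma_center = 2, sigma_surround = 3.5,
                        grid_size = 25)
  expect_gt(sum(kx * hp$labels[["hp001a"]]$grid), 0)
})

test_that("virtual neurons respond per their contracts", {
  cf <- crf(c(4, 2), 1.5, 1.5)
  hp <- gen_halfplane_labels(4, 9)
  ideal <- virtual_neuron("ideal_fg", crf = cf)
  sp <- simulate_responses(ideal, hp, n_trials = 3, seed = 1)
  tot <- spike_totals(sp, names(hp$labels))
  cls <- vapply(hp$labels, classify_stimulus_fg, character(1), crf = cf)
  expect_equal(unname(tot), unname(ifelse(cls == "figure", 3, 0)))

  flat <- simulate_responses(virtual_neuron("non_fg", constant = 4), hp,
                             n_trials = 2, seed = 2)
  expect_true(all(flat$stim_count == 4))

  k <- matrix(0, 9, 9); k[5, 2] <- 1
  rl <- virtual_neuron("rectified_linear", kernel = k, gain = 3)
  spr <- simulate_responses(rl, hp, n_trials = 1, seed = 3)
  drive <- vapply(hp$labels, function(l) sum(k * l$grid), numeric(1))
  expect_equal(unname(spike_totals(spr, names(hp$labels))),
               unname(round(3 * pmax(0, drive))))

  en <- virtual_neuron("energy", kernel = k, gain = 3)
  spe <- simulate_responses(en, hp, n_trials = 1, seed = 3)
  expect_equal(unname(spike_totals(spe, names(hp$labels))),
               unname(round(3 * abs(drive))))

  # determinism and Poisson reproducibility
  p1 <- simulate_responses(virtual_neuron("rectified_linear", kernel = k,
                                          gain = 5, noise = "poisson"),
                           hp, n_trials = 5, seed = 11)
  p2 <- simulate_responses(virtual_neuron("rectified_linear", kernel = k,
                                          gain = 5, noise = "poisson"),
                           hp, n_trials = 5, seed = 11)
  expect_identical(p1, p2)
  expect_error(simulate_responses(rl, gen_halfplane_labels(2, 7)),
               "grid")
})

test_that("grating maps peak at the CRF center and flatten at zero gain", {
  tc <- crf(c(13.1, 8.6), 3, 3, amplitude = 10, baseline = 0)
  m <- gen_grating_response_map(tc, 25, 5)
  peak <- which(m$map == max(m$map), arr.ind = TRUE)
  pr <- m$positions$row[peak]; pc <- m$positions$col[peak]
  d <- sqrt((m$positions$row - 13.1)^2 + (m$positions$col - 8.6)^2)
  expect_equal(sqrt((pr - 13.1)^2 + (pc - 8.6)^2), min(d))
  z <- gen_grating_response_map(tc, 25, 5, gain = 0)
  expect_equal(max(abs(z$map)), 0)
})
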