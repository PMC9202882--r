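test_that("the STA model response is rectified and homogeneous in its weight", {
  k <- matrix(rep(c(1, -1), length.out = 9), 3, 3)
  lab <- left_half_label(3)
  expect_equal(sta_model_response(k, lab, 0), 0)
  d <- sum(k * lab$grid)
  expect_equal(sta_model_response(k, lab, 2), max(0, 2 * d))
  neg <- fg_label(-lab$grid, "neg")
  if (sum(k * neg$grid) < 0)
    expect_equal(sta_model_response(k, neg, 3), 0)
  expect_equal(sta_model_response(k, lab, 4),
               2 * sta_model_response(k, lab, 2))
})

test_that("the STA model recovers its own generating weight", {
  lb <- gen_curved_labels(40, 11, 1.5, seed = 11)
  k <- make_dog_kernel(center = c(5, 4), orientation = 0.3,
                       sigma_center = 1.5, sigma_surround = 2.5,
                       grid_size = 11)
  w_true <- 6
  sp <- simulate_responses(
    virtual_neuron("rectified_linear", kernel = k, gain = w_true * 100),
    lb, n_trials = 1, seed = 12)
  fit <- fit_sta_model(k, lb, sp)
  expect_equal(fit$w_sta, w_true * 100, tolerance = 0.01)
  expect_gt(fit$pearson_r, 0.999)
  # a flat cell gives no usable correlation
  spf <- simulate_responses(
    virtual_neuron("non_fg", constant = 5, noise = "poisson"),
    lb, n_trials = 10, seed = 13)
  ff <- fit_sta_model(k, lb, spf)
  expect_lt(abs(ff$pearson_r), 0.35)
})

test_that("a neuron's own STA predicts it on noiseless data", {
  lb <- gen_curved_labels(40, 11, 1.5, seed = 14)
  k <- make_dog_kernel(center = c(5, 5), orientation = 1,
                       sigma_center = 1.5, sigma_surround = 2.5,
                       grid_size = 11)
  sp <- simulate_responses(
    virtual_neuron("rectified_linear", kernel = k, gain = 100),
    lb, n_trials = 1, seed = 15)
  sta <- rffg_sta(lb, sp, n_perm = 0)
  fit <- fit_sta_model(sta, lb, sp)
  expect_gt(fit$pearson_r, 0.9)
})

test_that("the joint model never fits worse and reduces exactly without STC terms", {
  lb <- gen_curved_labels(40, 11, 1.5, seed = 16)
  k <- make_dog_kernel(center = c(5, 4), orientation = 0.5,
                       sigma_center = 1.5, sigma_surround = 2.5,
                       grid_size = 11)
  for (kind in c("rectified_linear", "energy")) {
    sp <- simulate_responses(
      virtual_neuron(kind, kernel = k, gain = 50, noise = "poisson"),
      lb, n_trials = 10, seed = 17)
    sta <- rffg_sta(lb, sp, n_perm = 0)
    stc <- significant_stcs(rffg_stc(lb, sp, sta), lb, sp,
                            n_rand = 100, seed = 18)
    m1 <- fit_sta_model(sta, lb, sp)
    m2 <- fit_sta_stc_model(sta, stc, lb, sp)
    expect_lte(m2$rmse, m1$rmse + 1e-12)
  }
  # no significant kernels: identical to the STA fit
  spn <- counts_table(names(lb$labels), 3, n_trials = 2)
  stan <- rffg_sta(lb, spn, n_perm = 0)
  stcn <- rffg_stc(lb, spn, stan)   # all-zero spectrum, nothing flagged
  m1 <- fit_sta_model(stan, lb, spn)
  m2 <- fit_sta_stc_model(stan, stcn, lb, spn)
  expect_equal(m2$w_sta, m1$w_sta)
  expect_equal(m2$rmse, m1$rmse)
  expect_length(m2$w_stc_pos, 0)
})

test_that("STC terms help energy cells but not linear cells", {
  lb <- gen_curved_labels(50, 13, 1.5, seed = 19)
  ik <- ideal_rffg(lb, crf(c(6, 3), 2, 2), "figure")$grid
  k <- ik / sqrt(sum(ik^2))
  # purely linear cell: no gain from quadratic terms
  spl <- simulate_responses(
    virtual_neuron("linear", kernel = k, gain = 20, offset = 8),
    lb, n_trials = 10, seed = 20)
  stal <- rffg_sta(lb, spl, n_perm = 0)
  stcl <- significant_stcs(rffg_stc(lb, spl, stal), lb, spl,
                           n_rand = 100, seed = 21)
  d_lin <- fit_sta_stc_model(stal, stcl, lb, spl)$pearson_r -
    fit_sta_model(stal, lb, spl)$pearson_r
  expect_lt(abs(d_lin), 0.02)
  # energy cell: the quadratic subspace carries the response
  spe <- simulate_responses(virtual_neuron("energy", kernel = k, gain = 30),
                            lb, n_trials = 10, seed = 22)
  stae <- rffg_sta(lb, spe, n_perm = 0)
  stce <- significant_stcs(rffg_stc(lb, spe, stae), lb, spe,
                           n_rand = 100, seed = 23)
  r_sta <- fit_sta_model(stae, lb, spe)$pearson_r
  r_both <- fit_sta_stc_model(stae, stce, lb, spe)$pearson_r
  expect_gt(r_both, r_sta + 0.2)
})

test_that("the linearity diagnostic separates linear from energy mechanisms", {
  # uniform-orientation ensemble: the bin-mean projection is closest to
  # linear in bin rank, which bounds what a linear cell can score
  lbh <- gen_halfplane_labels(60, 13)
  kh <- make_dog_kernel(center = c(6, 5), orientation = 0.4,
                        sigma_center = 2, sigma_surround = 3, grid_size = 13)
  sph <- simulate_responses(
    virtual_neuron("linear", kernel = kh, gain = 100, offset = 4),
    lbh, n_trials = 1, seed = 25)
  dl <- linearity_diagnostic(kh, lbh, sph)
  expect_gt(dl$r_squared, 0.9)
  expect_gt(dl$slope, 0)
  lb <- gen_curved_labels(60, 13, 1.5, seed = 24)
  k <- make_dog_kernel(center = c(6, 5), orientation = 0.4,
                       sigma_center = 2, sigma_surround = 3, grid_size = 13)
  # probabilities are proper distributions
  expect_equal(sum(dl$curve$p_stim), 1)
  expect_equal(sum(dl$curve$p_stim_spike), 1)
  # energy cell against its own top STC kernel: U-shaped, low linear fit
  spe <- simulate_responses(virtual_neuron("energy", kernel = k, gain = 100),
                            lb, n_trials = 1, seed = 26)
  stae <- rffg_sta(lb, spe, n_perm = 0)
  stce <- rffg_stc(lb, spe, stae)
  de <- linearity_diagnostic(matrix(stce$eigenvectors[, 1], 13, 13), lb, spe)
  expect_lt(de$r_squared, 0.5)
  mid <- de$curve$ratio[5]
  expect_true(de$curve$ratio[1] > mid && de$curve$ratio[10] > mid)
  # uniform rates: flat curve at ratio 1
  spu <- counts_table(names(lb$labels), 3, n_trials = 2)
  du <- linearity_diagnostic(k, lb, spu)
  expect_equal(du$curve$ratio, rep(1, 10), tolerance = 1e-12)
})
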