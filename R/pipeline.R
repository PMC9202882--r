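# End-to-end orchestration: simulate a virtual neuron on a synthetic
# ensemble, then run the CRF, STA, AF, STC, model and metric stages,
# writing every stage's outputs and provenance to a run directory.

#' Run the full synthetic-to-metrics pipeline
#'
#' Executes the selected stages in order (simulate, crf, sta, af, stc,
#' model, metrics, validate) on a synthetic virtual neuron, writing each
#' stage's outputs (kernel TSVs with JSON sidecars, CSV tables) plus a
#' \code{summary.json} to \code{out_dir}. Per-stage seeds are derived from
#' the master seed as \code{seed + stage index}; identical configs and
#' seeds give identical outputs.
#'
#' @param config Named list (or path to a JSON file) with entries, all
#'   optional: \code{grid_size} (25), \code{n_labels} (105 base curves),
#'   \code{curvature_sd} (2), \code{neuron} (\code{"rectified_linear"},
#'   \code{"energy"}, \code{"ideal_fg"} or \code{"non_fg"}), \code{gain}
#'   (20), \code{noise} (\code{"none"}), \code{n_trials} (10),
#'   \code{n_perm} (1000; must be >= 1), \code{conv_step} (20),
#'   \code{conv_reps} (100), \code{n_rand_stc} (1000), \code{crf_center}
#'   (cells, default 3 cells left of the patch center), \code{crf_sd} (3),
#'   \code{stages} (character subset), \code{seed} (1).
#' @param out_dir Run directory (created; must not exist unless
#'   \code{overwrite}).
#' @param overwrite Allow writing into an existing directory.
#' @return Invisibly, the summary list written to \code{summary.json}.
#' @export
run_pipeline <- function(config = list(), out_dir, overwrite = FALSE) {
  if (is.character(config) && length(config) == 1)
    config <- jsonlite::fromJSON(config, simplifyVector = TRUE)
  defaults <- list(grid_size = 25, n_labels = 105, curvature_sd = 2,
                   neuron = "rectified_linear", gain = 20, noise = "none",
                   n_trials = 10, n_perm = 1000, conv_step = 20,
                   conv_reps = 100, n_rand_stc = 1000,
                   crf_center = NULL, crf_sd = 3,
                   stages = c("simulate", "crf", "sta", "af", "stc",
                              "model", "metrics"),
                   seed = 1L)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("run_pipeline: unknown config entries: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  cfg <- utils::modifyList(defaults, config)
  if (cfg$n_perm < 1)
    stop("run_pipeline: n_perm must be >= 1", call. = FALSE)
  if (!all(cfg$stages %in% defaults$stages))
    stop("run_pipeline: unknown stage(s): ",
         paste(setdiff(cfg$stages, defaults$stages), collapse = ", "),
         call. = FALSE)
  if (dir.exists(out_dir) && !overwrite)
    stop("run_pipeline: out_dir exists; set overwrite = TRUE", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ctr <- (cfg$grid_size - 1) / 2
  if (is.null(cfg$crf_center)) cfg$crf_center <- c(ctr, ctr - 4)
  seed_of <- function(stage)
    as.integer(cfg$seed + match(stage, defaults$stages))
  summary <- list(config = cfg[setdiff(names(cfg), "stages")],
                  stages = list())
  stage_failed <- function(stage, e) {
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    stop(sprintf("run_pipeline: stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  }

  # -- simulate ------------------------------------------------------------
  labels <- gen_curved_labels(cfg$n_labels, cfg$grid_size, cfg$curvature_sd,
                              seed = seed_of("simulate"))
  true_crf <- crf(cfg$crf_center, cfg$crf_sd, cfg$crf_sd)
  truth <- make_dog_kernel(center = cfg$crf_center,
                           orientation = atan2(ctr - cfg$crf_center[1],
                                               ctr - cfg$crf_center[2]),
                           sigma_center = cfg$crf_sd,
                           sigma_surround = 2 * cfg$crf_sd,
                           grid_size = cfg$grid_size)
  neuron <- switch(cfg$neuron,
    rectified_linear = virtual_neuron("rectified_linear", kernel = truth,
                                      gain = cfg$gain, noise = cfg$noise),
    energy = virtual_neuron("energy", kernel = truth, gain = cfg$gain,
                            noise = cfg$noise),
    ideal_fg = virtual_neuron("ideal_fg", crf = true_crf,
                              noise = cfg$noise),
    non_fg = virtual_neuron("non_fg", constant = cfg$gain,
                            noise = cfg$noise),
    stop("run_pipeline: unknown neuron kind ", cfg$neuron, call. = FALSE))
  spikes <- simulate_responses(neuron, labels, n_trials = cfg$n_trials,
                               seed = seed_of("simulate"))
  if ("simulate" %in% cfg$stages) {
    write_spike_table(spikes, file.path(out_dir, "spikes.csv"))
    write_labels(labels, file.path(out_dir, "labels"))
    summary$stages$simulate <- list(n_labels = labels$N,
                                    total_spikes = sum(spikes$stim_count),
                                    seed = seed_of("simulate"))
  }

  # -- crf -----------------------------------------------------------------
  crf_fit <- true_crf
  if ("crf" %in% cfg$stages) {
    map <- gen_grating_response_map(true_crf, cfg$grid_size, gain = 10,
                                    seed = seed_of("crf"))
    crf_fit <- tryCatch(fit_crf(map$map, map$positions),
                        error = function(e) stage_failed("crf", e))
    summary$stages$crf <- list(center = crf_fit$center,
                               sd_major = crf_fit$sd_major,
                               sd_minor = crf_fit$sd_minor,
                               responsiveness_p =
                                 as.numeric(responsiveness_test(spikes)))
  }

  # -- sta -----------------------------------------------------------------
  sta <- tryCatch(
    rffg_sta(labels, spikes, n_perm = cfg$n_perm,
             convergence = "sta" %in% cfg$stages,
             step = max(1, min(cfg$conv_step, floor(labels$N / 6))),
             reps = cfg$conv_reps,
             seed = seed_of("sta")),
    error = function(e) stage_failed("sta", e))
  if ("sta" %in% cfg$stages) {
    write_kernel(sta, file.path(out_dir, "kernel_sta.tsv"))
    summary$stages$sta <- list(magnitude = sta$magnitude,
                               p_perm = sta$p_perm,
                               convergence_ratio = sta$convergence_ratio,
                               effective = sta$effective)
  }

  # -- af ------------------------------------------------------------------
  if ("af" %in% cfg$stages) {
    af <- tryCatch(
      rffg_af(labels, spikes, af_config(seed = seed_of("af"))),
      error = function(e) stage_failed("af", e))
    write_kernel(af, file.path(out_dir, "kernel_af.tsv"))
    summary$stages$af <- list(
      rmse = af$rmse,
      cos_af_sta = tryCatch(cosine_similarity(af, sta),
                            error = function(e) NA_real_))
  }

  # -- stc -----------------------------------------------------------------
  stc <- NULL
  if ("stc" %in% cfg$stages) {
    stc <- tryCatch({
      s0 <- rffg_stc(labels, normalize_spikes(spikes, names(labels$labels)),
                     sta)
      significant_stcs(s0, labels, spikes, n_rand = cfg$n_rand_stc,
                       seed = seed_of("stc"))
    }, error = function(e) stage_failed("stc", e))
    sig_ranks <- stc$rank_labels[isTRUE_vec(stc$significant)]
    for (rk in sig_ranks)
      write_kernel(stc_kernel(stc, rk),
                   file.path(out_dir, sprintf("kernel_stc_%s.tsv",
                                              gsub("\\+", "p",
                                                   gsub("-", "m", rk)))))
    summary$stages$stc <- list(n_significant = length(sig_ranks),
                               significant_ranks = as.list(sig_ranks))
  }

  # -- model ---------------------------------------------------------------
  if ("model" %in% cfg$stages) {
    m_sta <- tryCatch(fit_sta_model(sta, labels, spikes),
                      error = function(e) stage_failed("model", e))
    m_both <- if (!is.null(stc))
      fit_sta_stc_model(sta, stc, labels, spikes) else m_sta
    summary$stages$model <- list(r_sta = m_sta$pearson_r,
                                 r_sta_stc = m_both$pearson_r,
                                 delta_r = m_both$pearson_r - m_sta$pearson_r,
                                 rmse_sta = m_sta$rmse,
                                 rmse_sta_stc = m_both$rmse)
  }

  # -- metrics -------------------------------------------------------------
  if ("metrics" %in% cfg$stages) {
    met <- tryCatch({
      pref <- if (sum(sta$grid^2) > 0) {
        rc <- floor(crf_fit$center + 0.5)
        if (sta$grid[rc[1] + 1, rc[2] + 1] >= 0) "figure" else "ground"
      } else "figure"
      list(preference = pref,
           pr_ratio = tryCatch(pr_ratio(sta, pref),
                               error = function(e) NA_real_),
           overlap_ratio = tryCatch(overlap_ratio(crf_fit, sta, pref),
                                    error = function(e) NA_real_),
           cos_sta_ideal = tryCatch(
             cosine_similarity(sta, ideal_rffg(labels, crf_fit, pref)),
             error = function(e) NA_real_))
    }, error = function(e) stage_failed("metrics", e))
    summary$stages$metrics <- met
  }

  # -- validate ------------------------------------------------------------
  if ("validate" %in% cfg$stages) {
    rep <- tryCatch(run_validation(truth, labels, seed = seed_of("validate")),
                    error = function(e) stage_failed("validate", e))
    utils::write.csv(as.data.frame(rep),
                     file.path(out_dir, "validation.csv"), row.names = FALSE)
    summary$stages$validate <- as.list(rep[1, ])
  }

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(summary)
}
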