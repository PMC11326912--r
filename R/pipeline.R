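#' Default pipeline configuration
#'
#' All stage parameters with their standard values: 20-ms behavioral and
#' 80-ms neurometric bins shifted every 1 ms, a 21-ms SDF kernel, 500
#' behavioral and 1000 neurometric bootstrap iterations, alpha = 0.05 for
#' neuron selection, the 90° spatial classification window, the −50–0 ms
#' presaccadic window, and the 0–300 ms capture integration range. Simulation
#' sub-lists give the generator settings for a young-like and an adult-like
#' synthetic dataset.
#'
#' @return A nested named list; override entries and pass to
#'   [run_pipeline()].
#' @export
default_config <- function() {
  list(
    seed = 1,
    out_dir = NULL,
    window_deg = 90,
    behavior = list(bin_width_ms = 20, step_ms = 1, min_valid = 10,
                    n_boot = 500, level = 0.75, capture_range = c(0, 300)),
    neural = list(sigma_ms = 21, bin_width_ms = 80, step_ms = 1,
                  rpt_range = c(70, 300), min_n = 20, n_boot = 1000,
                  alpha = 0.05, presac_window = c(-50, 0)),
    simulate = list(
      n_trials = 5000,
      n_neurons = 8,
      young = list(true_fit = list(b = 0.2, ar = 0.85, cl = 95, dl = 8,
                                   cr = 165, dr = 14),
                   neuron = list(cue_amp_hz = 30, presac_amp_hz = 10)),
      adult = list(true_fit = list(b = 0.15, ar = 0.92, cl = 90, dl = 8,
                                   cr = 140, dr = 12),
                   neuron = list(cue_amp_hz = 20, presac_amp_hz = 18))
    )
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Run the full synthetic-to-analysis pipeline
#'
#' Chains the stages for two synthetic developmental stages (young-like and
#' adult-like): trial-table generation, tachometric estimation and fitting
#' with bootstrap CIs, antisaccade spike-train generation, pooled neurometric
#' curve, and the superposition-model bias curve. All randomness derives
#' from the single top-level seed; reports embed the fully resolved
#' configuration, so two runs with the same config are identical.
#'
#' @param config A nested list of overrides over [default_config()], or a
#'   path to a YAML file of the same shape.
#' @return A list (one element per stage label) with `trials`, `curve`,
#'   `fit`, `boot`, `spikes`, `centered`, `neurometric`, `bias`, plus the
#'   resolved `config`. When `config$out_dir` is set, CSV/JSON reports are
#'   written there.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(default_config(), config)
  out <- list(config = cfg)
  stage_seed <- function(k) (cfg$seed * 101 + k) %% .Machine$integer.max

  for (k in seq_along(c("young", "adult"))) {
    stage <- c("young", "adult")[k]
    scfg <- cfg$simulate[[stage]]
    tf <- do.call(sigmoid_fit, scfg$true_fit)
    bp <- behavior_sim_params(true_fit = tf, n_trials = cfg$simulate$n_trials,
                              stage = stage, seed = stage_seed(k))
    trials <- generate_behavior(bp) |>
      classify_saccade(window_deg = cfg$window_deg)
    bcfg <- cfg$behavior
    curve <- tachometric_curve(trials, bin_width_ms = bcfg$bin_width_ms,
                               step_ms = bcfg$step_ms)
    boot <- bootstrap_behavior(trials, n_boot = bcfg$n_boot,
                               seed = stage_seed(k + 10),
                               bin_width_ms = bcfg$bin_width_ms,
                               step_ms = bcfg$step_ms,
                               min_valid = bcfg$min_valid,
                               level = bcfg$level,
                               rpt_range = bcfg$capture_range)
    np <- do.call(neuron_sim_params, c(scfg$neuron, list(seed = stage_seed(k))))
    spikes <- purrr::map(seq_len(cfg$simulate$n_neurons), function(j) {
      bp_j <- bp; bp_j$seed <- as.integer(stage_seed(k * 1000 + j))
      tr_j <- classify_saccade(generate_behavior(bp_j), cfg$window_deg)
      generate_antisaccade_neuron(np, tr_j, neuron_id = sprintf("%s_%02d", stage, j),
                                  seed = stage_seed(k * 1000 + j) + 1)
    }) |>
      dplyr::bind_rows()
    ncfg <- cfg$neural
    centered <- pool_and_center(spikes, presac_window = ncfg$presac_window)
    nmc <- neurometric_curve(centered, bin_width_ms = ncfg$bin_width_ms,
                             step_ms = ncfg$step_ms,
                             rpt_range = ncfg$rpt_range, min_n = ncfg$min_n,
                             n_boot = ncfg$n_boot, seed = stage_seed(k + 20))
    prof <- generator_profiles(np)
    bias <- bias_curve(prof$cue, prof$sac,
                       rpt_grid_ms = seq(ncfg$rpt_range[1], ncfg$rpt_range[2], 1),
                       window = ncfg$presac_window)
    out[[stage]] <- list(trials = trials, curve = curve, fit = boot$fit,
                         boot = boot, spikes = spikes, centered = centered,
                         neurometric = nmc, bias = bias)
  }

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    for (stage in c("young", "adult")) {
      s <- out[[stage]]
      write_trials_csv(s$trials, file.path(cfg$out_dir,
                                           paste0("trials_", stage, ".csv")))
      write_spikes_jsonl(s$spikes, file.path(cfg$out_dir,
                                             paste0("spikes_", stage, ".jsonl")))
      readr::write_csv(s$curve, file.path(cfg$out_dir,
                                          paste0("tachometric_", stage, ".csv")))
      readr::write_csv(s$neurometric,
                       file.path(cfg$out_dir,
                                 paste0("neurometric_", stage, ".csv")))
      readr::write_csv(s$bias, file.path(cfg$out_dir,
                                         paste0("bias_", stage, ".csv")))
      jsonlite::write_json(
        list(stage = stage, config = cfg,
             fit = setNames(as.list(tidy(s$fit)$estimate), tidy(s$fit)$term),
             metrics = s$boot$ci),
        file.path(cfg$out_dir, paste0("behavior_", stage, ".json")),
        auto_unbox = TRUE, digits = NA, null = "null"
      )
    }
  }
  out
}
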