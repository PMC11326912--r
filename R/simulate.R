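#' Parameters for the behavioral trial generator
#'
#' Describes the ground-truth conditions behind a synthetic antisaccade
#' session: a true tachometric curve, per-variant reaction-time
#' distributions, angular scatter of saccade endpoints, and the cue-location
#' geometry (eight locations on a circle, cardinal locations used on ~75% of
#' trials).
#'
#' @param true_fit Ground-truth accuracy curve, a [sigmoid_fit()].
#' @param lapse_rate Probability that a trial is answered with a uniformly
#'   random saccade direction regardless of rPT, in `[0, 1]`. The default is
#'   0 because the asymptote `ar` of `true_fit` already encodes lapse-limited
#'   performance.
#' @param rt_means_ms,rt_sds_ms Named per-variant reaction-time mean/SD (ms);
#'   RTs are truncated-normal on \[50, 600\] ms. Defaults place the pooled
#'   rPT coverage over roughly 0–400 ms.
#' @param dir_concentration Von Mises concentration of saccade endpoints
#'   around the chosen goal (higher = more precise; 20 corresponds to ~13°
#'   angular SD).
#' @param n_trials Number of trials to generate.
#' @param cardinal_fraction Probability that the cue appears at a cardinal
#'   location (default 0.75).
#' @param include_gap200 Also draw the 200-ms gap variant (default `FALSE`;
#'   when `FALSE` the three standard variants are drawn uniformly).
#' @param stage Stage label attached to every trial (`"young"` or
#'   `"adult"`).
#' @param seed Integer seed; generation is a pure function of
#'   (parameters, seed).
#' @return An object of class `behavior_sim_params`.
#' @export
behavior_sim_params <- function(
    true_fit = sigmoid_fit(b = 0.2, ar = 0.9, cl = 95, dl = 8, cr = 150, dr = 12),
    lapse_rate = 0,
    rt_means_ms = c(overlap = 130, zero_gap = 200, gap100 = 250, gap200 = 350),
    rt_sds_ms = c(overlap = 70, zero_gap = 70, gap100 = 70, gap200 = 70),
    dir_concentration = 20,
    n_trials = 5000,
    cardinal_fraction = 0.75,
    include_gap200 = FALSE,
    stage = "young",
    seed = 1) {
  stopifnot(inherits(true_fit, "sigmoid_fit"))
  check_number(lapse_rate, "lapse_rate", 0, 1)
  check_number(cardinal_fraction, "cardinal_fraction", 0, 1)
  check_number(dir_concentration, "dir_concentration", 0)
  check_number(n_trials, "n_trials", 1)
  conds <- c("overlap", "zero_gap", "gap100", if (include_gap200) "gap200")
  if (!all(conds %in% names(rt_means_ms)) ||
      !all(conds %in% names(rt_sds_ms))) {
    abort("`rt_means_ms` and `rt_sds_ms` must name every gap condition used.")
  }
  if (any(rt_means_ms <= 0) || any(rt_sds_ms <= 0)) {
    abort("Reaction-time parameters must be positive.")
  }
  structure(
    list(true_fit = true_fit, lapse_rate = lapse_rate,
         rt_means_ms = rt_means_ms, rt_sds_ms = rt_sds_ms,
         dir_concentration = dir_concentration, n_trials = as.integer(n_trials),
         cardinal_fraction = cardinal_fraction,
         include_gap200 = include_gap200, stage = stage,
         seed = as.integer(seed)),
    class = "behavior_sim_params"
  )
}

#' Generate a synthetic antisaccade trial table
#'
#' Draws, per trial: a timing variant (uniform over the active variants), a
#' cue location (cardinal with probability `cardinal_fraction`), an RT from
#' the variant's truncated-normal distribution, the rPT by the variant's
#' offset rule, and a saccade direction. The saccade is aimed at the target
#' with probability given by the true tachometric curve at that trial's rPT,
#' at the cue otherwise (exogenous capture), or — on lapse trials — in a
#' uniformly random direction; aimed saccades get von Mises angular scatter.
#'
#' @param params A [behavior_sim_params()] object.
#' @return A tibble with one row per trial: `trial_id`, `stage`,
#'   `gap_condition`, `cue_dir_deg`, `target_dir_deg`, `saccade_dir_deg`,
#'   `rt_ms`, `rpt_ms`.
#' @examples
#' trials <- generate_behavior(behavior_sim_params(n_trials = 200, seed = 7))
#' @export
generate_behavior <- function(params) {
  stopifnot(inherits(params, "behavior_sim_params"))
  p <- params
  n <- p$n_trials
  conds <- c("overlap", "zero_gap", "gap100", if (p$include_gap200) "gap200")
  withr::with_seed(p$seed, {
    gap <- sample(conds, n, replace = TRUE)
    cardinal <- runif(n) < p$cardinal_fraction
    cue <- ifelse(cardinal,
                  sample(c(0, 90, 180, 270), n, replace = TRUE),
                  sample(c(45, 135, 225, 315), n, replace = TRUE))
    rt <- rtruncnorm(n, unname(p$rt_means_ms[gap]), unname(p$rt_sds_ms[gap]),
                     50, 600)
    rpt <- rt + rpt_offset_ms(gap)
    target <- (cue + 180) %% 360
    p_correct <- eval_sigmoid(p$true_fit, rpt)
    lapse <- runif(n) < p$lapse_rate
    aimed_correct <- runif(n) < p_correct
    scatter <- rvonmises(n, 0, p$dir_concentration)
    saccade <- ifelse(aimed_correct, target + scatter, cue + scatter)
    saccade[lapse] <- runif(sum(lapse), 0, 360)
    tibble::tibble(
      trial_id = seq_len(n),
      stage = p$stage,
      gap_condition = gap,
      cue_dir_deg = cue,
      target_dir_deg = target,
      saccade_dir_deg = saccade %% 360,
      rt_ms = rt,
      rpt_ms = rpt
    )
  })
}

# Solve the rise/decay time constants of the difference-of-exponentials cue
# transient f(s) = exp(-s/tau_d) - exp(-s/tau_r) from its two landmarks:
# the peak time and the post-peak half-maximum time (both relative to
# response onset).
solve_transient_taus <- function(peak_rel, half_rel) {
  stopifnot(half_rel > peak_rel, peak_rel > 0)
  peak_time <- function(tau_r, tau_d) {
    tau_r * tau_d / (tau_d - tau_r) * log(tau_d / tau_r)
  }
  tau_r_for <- function(tau_d) {
    uniroot(function(tr) peak_time(tr, tau_d) - peak_rel,
            lower = 1e-6, upper = tau_d * (1 - 1e-9), tol = 1e-10)$root
  }
  ratio_at_half <- function(tau_d) {
    tau_r <- tau_r_for(tau_d)
    f <- function(s) exp(-s / tau_d) - exp(-s / tau_r)
    f(half_rel) / f(peak_rel) - 0.5
  }
  # the alpha-function limit (tau_r -> tau_d) is the fastest decay this
  # family supports for a given peak time; reject infeasible landmarks
  lo <- peak_rel * 1.001
  if (ratio_at_half(lo) > 0) {
    abort(paste0(
      "Infeasible cue-transient landmarks: with this peak time the ",
      "difference-of-exponentials cannot decay to half maximum that early; ",
      "increase cue_halfdecay_ms or reduce cue_peak_ms."))
  }
  tau_d <- uniroot(ratio_at_half, lower = lo, upper = 1e5, tol = 1e-8)$root
  tau_r <- tau_r_for(tau_d)
  f_peak <- exp(-peak_rel / tau_d) - exp(-peak_rel / tau_r)
  list(tau_r = tau_r, tau_d = tau_d, f_peak = f_peak)
}

#' Parameters for the synthetic visuomotor neuron generators
#'
#' Shape parameters of a prefrontal visuomotor (VM) neuron's rate function:
#' a baseline, an alpha-like cue transient (difference of exponentials
#' parameterised by onset latency, peak time and post-cue half-decay time),
#' a sustained delay-period elevation (memory task only), and a presaccadic
#' linear ramp peaking at saccade onset. Responses on trials with the cue
#' outside the response field are scaled by `out_of_rf_gain`.
#'
#' @param baseline_hz Baseline firing rate (spikes/s).
#' @param cue_amp_hz Peak amplitude of the cue transient above baseline.
#' @param cue_latency_ms Response onset latency after cue onset.
#' @param cue_peak_ms Time of the transient peak after cue onset (default
#'   125, i.e. within the typical 100–150 ms range).
#' @param cue_halfdecay_ms Post-cue time at which the transient has decayed
#'   to half its peak (default 400).
#' @param delay_hz Sustained delay-period elevation (memory-guided task only).
#' @param presac_amp_hz Amplitude of the presaccadic ramp at saccade onset.
#' @param presac_buildup_ms Ramp duration before saccade onset (default 200).
#' @param out_of_rf_gain Multiplier on evoked components for out-of-RF
#'   trials, in `[0, 1]`.
#' @param n_trials_odr,n_trials_anti Trial counts for the two tasks
#'   (defaults 71 and 110, typical per-neuron counts).
#' @param rf_dir_deg Response-field direction (degrees).
#' @param odr_rt_mean_ms,odr_rt_sd_ms Memory-guided saccade RT distribution.
#' @param seed Integer seed.
#' @return An object of class `neuron_sim_params` (with solved transient
#'   time constants attached).
#' @export
neuron_sim_params <- function(
    baseline_hz = 10, cue_amp_hz = 30, cue_latency_ms = 50, cue_peak_ms = 125,
    cue_halfdecay_ms = 400, delay_hz = 5, presac_amp_hz = 15,
    presac_buildup_ms = 200, out_of_rf_gain = 0.1,
    n_trials_odr = 71, n_trials_anti = 110, rf_dir_deg = 0,
    odr_rt_mean_ms = 250, odr_rt_sd_ms = 50, seed = 1) {
  for (nm in c("baseline_hz", "cue_amp_hz", "delay_hz", "presac_amp_hz")) {
    check_number(get(nm), nm, 0)
  }
  check_number(out_of_rf_gain, "out_of_rf_gain", 0, 1)
  check_number(presac_buildup_ms, "presac_buildup_ms", 1)
  if (!(cue_latency_ms < cue_peak_ms && cue_peak_ms < cue_halfdecay_ms)) {
    abort("Need cue_latency_ms < cue_peak_ms < cue_halfdecay_ms.")
  }
  taus <- solve_transient_taus(cue_peak_ms - cue_latency_ms,
                               cue_halfdecay_ms - cue_latency_ms)
  structure(
    list(baseline_hz = baseline_hz, cue_amp_hz = cue_amp_hz,
         cue_latency_ms = cue_latency_ms, cue_peak_ms = cue_peak_ms,
         cue_halfdecay_ms = cue_halfdecay_ms, delay_hz = delay_hz,
         presac_amp_hz = presac_amp_hz,
         presac_buildup_ms = presac_buildup_ms,
         out_of_rf_gain = out_of_rf_gain,
         n_trials_odr = as.integer(n_trials_odr),
         n_trials_anti = as.integer(n_trials_anti),
         rf_dir_deg = rf_dir_deg,
         odr_rt_mean_ms = odr_rt_mean_ms, odr_rt_sd_ms = odr_rt_sd_ms,
         taus = taus, seed = as.integer(seed)),
    class = "neuron_sim_params"
  )
}

# cue transient (spikes/s) at time s after cue onset
cue_transient_hz <- function(s_ms, p) {
  s <- s_ms - p$cue_latency_ms
  out <- numeric(length(s))
  pos <- !is.na(s) & s > 0
  out[pos] <- p$cue_amp_hz *
    (exp(-s[pos] / p$taus$tau_d) - exp(-s[pos] / p$taus$tau_r)) / p$taus$f_peak
  out
}

# presaccadic ramp (spikes/s) at time s relative to saccade onset; linear
# build-up over presac_buildup_ms, linear release over 100 ms after onset
presac_ramp_hz <- function(s_ms, p) {
  up <- pmax(1 + s_ms / p$presac_buildup_ms, 0) * (s_ms <= 0)
  down <- pmax(1 - s_ms / 100, 0) * (s_ms > 0)
  p$presac_amp_hz * (up + down)
}

# draw one inhomogeneous-Poisson spike train on [0, t_end] by thinning
draw_spikes <- function(rate_fun, t_end, rate_max) {
  n_cand <- rpois(1, rate_max * t_end / 1000)
  if (n_cand == 0) return(numeric(0))
  tt <- sort(runif(n_cand, 0, t_end))
  keep <- runif(n_cand) < rate_fun(tt) / rate_max
  tt[keep]
}

#' Generate a synthetic memory-guided (ODR) recording
#'
#' Simulates one neuron's trials of the oculomotor delayed response task:
#' 1000 ms fixation, a 500-ms cue at one of eight locations, a 1500-ms delay,
#' then a memory-guided saccade to the cue location. Spikes are an
#' inhomogeneous Poisson process whose rate is baseline plus — scaled by
#' `out_of_rf_gain` when the cue is outside the response field — the cue
#' transient, the sustained delay elevation, and the presaccadic ramp.
#'
#' @param params A [neuron_sim_params()] object.
#' @param neuron_id Identifier attached to every trial.
#' @param seed Seed for this recording (defaults to `params$seed`).
#' @return A tibble with one row per trial: identifiers, task/event times
#'   (`cue_on_ms`, `go_ms`, `saccade_on_ms`), geometry (`cue_dir_deg`,
#'   `rf_dir_deg`, `cue_in_rf`, `saccade_in_rf`), and a `spike_times_ms`
#'   list-column of sorted spike times relative to trial start.
#' @export
generate_odr_neuron <- function(params, neuron_id = "n1", seed = params$seed) {
  stopifnot(inherits(params, "neuron_sim_params"))
  p <- params
  n <- p$n_trials_odr
  locs <- seq(0, 315, by = 45)
  cue_on <- 1000; go <- cue_on + 500 + 1500
  withr::with_seed(seed, {
    cue_dir <- rep(locs, length.out = n)[sample.int(n)]
    rt <- rtruncnorm(n, p$odr_rt_mean_ms, p$odr_rt_sd_ms, 100, 600)
    sac_on <- go + rt
    gain <- ifelse(circ_dist(cue_dir, p$rf_dir_deg) < 22.5, 1, p$out_of_rf_gain)
    spikes <- purrr::map(seq_len(n), function(i) {
      rate <- function(t) {
        p$baseline_hz + gain[i] * (
          cue_transient_hz(t - cue_on, p) +
            p$delay_hz * (t >= cue_on + p$cue_latency_ms & t < sac_on[i]) +
            presac_ramp_hz(t - sac_on[i], p)
        )
      }
      rmax <- p$baseline_hz +
        (p$cue_amp_hz + p$delay_hz + p$presac_amp_hz) + 1e-9
      draw_spikes(rate, sac_on[i] + 300, rmax)
    })
    tibble::tibble(
      neuron_id = neuron_id, trial_id = seq_len(n), task = "odr",
      cue_dir_deg = cue_dir, rf_dir_deg = p$rf_dir_deg,
      cue_in_rf = gain == 1, saccade_in_rf = gain == 1,
      cue_on_ms = cue_on, go_ms = go, saccade_on_ms = sac_on,
      rpt_ms = sac_on - cue_on, outcome = "correct",
      spike_times_ms = spikes
    )
  })
}

#' Generate a synthetic antisaccade recording by superposition
#'
#' Simulates one neuron's antisaccade trials from a behavioral trial table.
#' The generative rule is the superposition conflict model itself: each
#' trial's rate is baseline, plus the cue transient aligned to cue onset when
#' the cue falls in the response field, plus the presaccadic ramp aligned to
#' saccade onset when the saccade lands in the response field. Trials engaging
#' neither component fire at baseline. This makes the model's bias prediction
#' the ground truth of the generated spike trains, enabling end-to-end
#' recovery tests against the neurometric pipeline.
#'
#' @inheritParams generate_odr_neuron
#' @param trials A behavioral trial table carrying `rpt_ms`, `rt_ms`,
#'   `gap_condition`, `cue_dir_deg`, `saccade_dir_deg` (e.g. from
#'   [generate_behavior()]); the first `n_trials_anti` rows are used.
#' @return A tibble with the same per-trial schema as
#'   [generate_odr_neuron()], `task = "antisaccade"`, plus the trial's
#'   `outcome` if present in `trials` (otherwise classified on the fly).
#' @export
generate_antisaccade_neuron <- function(params, trials, neuron_id = "n1",
                                        seed = params$seed) {
  stopifnot(inherits(params, "neuron_sim_params"), is.data.frame(trials))
  need <- c("rpt_ms", "rt_ms", "gap_condition", "cue_dir_deg",
            "saccade_dir_deg")
  if (!all(need %in% names(trials))) {
    abort(paste0("`trials` must carry columns: ", paste(need, collapse = ", ")))
  }
  p <- params
  if (nrow(trials) < p$n_trials_anti) {
    abort("`trials` has fewer rows than `n_trials_anti`.")
  }
  tr <- utils::head(trials, p$n_trials_anti)
  if (!"outcome" %in% names(tr)) tr <- classify_saccade(tr)
  n <- nrow(tr)
  go <- 1000
  cue_on <- go - rpt_offset_ms(tr$gap_condition)
  sac_on <- cue_on + tr$rpt_ms
  cue_in <- circ_dist(tr$cue_dir_deg, p$rf_dir_deg) < 22.5
  sac_in <- circ_dist(tr$saccade_dir_deg, p$rf_dir_deg) <= 22.5
  withr::with_seed(seed, {
    spikes <- purrr::map(seq_len(n), function(i) {
      rate <- function(t) {
        p$baseline_hz +
          (if (cue_in[i]) cue_transient_hz(t - cue_on[i], p) else 0) +
          (if (sac_in[i]) presac_ramp_hz(t - sac_on[i], p) else 0)
      }
      rmax <- p$baseline_hz + p$cue_amp_hz + p$presac_amp_hz + 1e-9
      draw_spikes(rate, sac_on[i] + 300, rmax)
    })
    tibble::tibble(
      neuron_id = neuron_id, trial_id = tr$trial_id %||% seq_len(n),
      task = "antisaccade",
      cue_dir_deg = tr$cue_dir_deg, rf_dir_deg = p$rf_dir_deg,
      cue_in_rf = cue_in, saccade_in_rf = sac_in,
      cue_on_ms = cue_on, go_ms = go, saccade_on_ms = sac_on,
      rpt_ms = tr$rpt_ms, outcome = tr$outcome,
      spike_times_ms = spikes
    )
  })
}

#' Closed-form response profiles of a synthetic neuron
#'
#' Returns the generator's cue-aligned and saccade-aligned rate profiles as
#' [response_profile()] objects, for use with the superposition conflict
#' model ("synthetic mode").
#'
#' @inheritParams generate_odr_neuron
#' @param t_cue_ms,t_sac_ms Time grids for the two profiles (ms, relative to
#'   cue onset and saccade onset respectively).
#' @return A list with elements `cue` and `sac`.
#' @export
generator_profiles <- function(params,
                               t_cue_ms = seq(-200, 800, by = 1),
                               t_sac_ms = seq(-400, 100, by = 1)) {
  stopifnot(inherits(params, "neuron_sim_params"))
  list(
    cue = response_profile(t_cue_ms,
                           params$baseline_hz + cue_transient_hz(t_cue_ms, params),
                           alignment = "cue_onset"),
    sac = response_profile(t_sac_ms,
                           params$baseline_hz + presac_ramp_hz(t_sac_ms, params),
                           alignment = "saccade_onset")
  )
}
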