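#' Time-indexed mean firing-rate profile
#'
#' A response profile is a mean rate trace on a uniform time grid, aligned
#' either to cue onset or to saccade onset. Profiles may come from the
#' population averages of recorded/simulated neurons (empirical mode) or
#' from the generator's closed-form shapes ([generator_profiles()]).
#'
#' @param t_ms Strictly increasing, uniformly spaced time grid (ms) relative
#'   to the alignment event.
#' @param rate_hz Non-negative mean rates (spikes/s).
#' @param alignment `"cue_onset"` or `"saccade_onset"`.
#' @return A tibble of class `response_profile`.
#' @export
response_profile <- function(t_ms, rate_hz,
                             alignment = c("cue_onset", "saccade_onset")) {
  alignment <- match.arg(alignment)
  if (length(t_ms) != length(rate_hz) || length(t_ms) < 2) {
    abort("`t_ms` and `rate_hz` must be equal-length vectors (>= 2 points).")
  }
  steps <- diff(t_ms)
  if (any(steps <= 0) || max(abs(steps - steps[1])) > 1e-8 * abs(steps[1])) {
    abort("`t_ms` must be strictly increasing with uniform spacing.")
  }
  if (any(rate_hz < 0)) abort("`rate_hz` must be non-negative.")
  structure(tibble::tibble(t_ms = t_ms, rate_hz = rate_hz),
            class = c("response_profile", class(tibble::tibble())),
            alignment = alignment)
}

#' Superimpose cue-driven and saccade-related profiles at a given rPT
#'
#' Places the cue-aligned profile on the saccade-aligned time axis for a
#' trial in which the cue led the saccade by `rpt_ms`: a point at time
#' `t_cue` after cue onset sits at `t_cue - rpt_ms` relative to saccade
#' onset. The shifted cue profile is linearly interpolated onto the
#' saccade-aligned grid; times outside its support take the profile's
#' baseline (its first grid value). Post-saccadic changes in the real
#' response are not modeled.
#'
#' @param cue_profile A [response_profile()] aligned to cue onset.
#' @param sac_profile A [response_profile()] aligned to saccade onset.
#' @param rpt_ms Cue-to-saccade interval (ms).
#' @return A tibble on the saccade-aligned grid: `t_ms`, `cue_hz` (shifted),
#'   `sac_hz`; attribute `coverage` gives the fraction of the grid covered by
#'   the cue profile's support (a shift with zero coverage is flagged with a
#'   warning).
#' @export
superimpose <- function(cue_profile, sac_profile, rpt_ms) {
  stopifnot(inherits(cue_profile, "response_profile"),
            inherits(sac_profile, "response_profile"))
  if (attr(cue_profile, "alignment") != "cue_onset" ||
      attr(sac_profile, "alignment") != "saccade_onset") {
    abort("Profiles must be cue_onset- and saccade_onset-aligned, in that order.")
  }
  grid <- sac_profile$t_ms
  t_cue <- grid + rpt_ms  # saccade-aligned time mapped back to cue-aligned
  inside <- t_cue >= min(cue_profile$t_ms) & t_cue <= max(cue_profile$t_ms)
  cue_hz <- rep(cue_profile$rate_hz[1], length(grid))
  if (any(inside)) {
    cue_hz[inside] <- approx(cue_profile$t_ms, cue_profile$rate_hz,
                             xout = t_cue[inside])$y
  } else {
    warn(sprintf("rpt = %g ms shifts the cue profile entirely off the grid.",
                 rpt_ms))
  }
  out <- tibble::tibble(t_ms = grid, cue_hz = cue_hz,
                        sac_hz = sac_profile$rate_hz)
  attr(out, "coverage") <- mean(inside)
  out
}

#' Presaccadic spatial bias of the superposition model
#'
#' The mean difference between the shifted cue-driven profile and the
#' saccade-aligned profile inside a presaccadic window (default −50 to 0 ms).
#' Positive values mean the cue-driven representation is stronger than the
#' goal-driven one just before movement onset (cue-dominant); negative
#' values favor the saccade goal.
#'
#' @inheritParams superimpose
#' @param window Presaccadic window `c(start, end)` in saccade-aligned ms.
#' @return Bias in spikes/s, or `NA_real_` (with a warning) if the
#'   saccade-aligned grid does not cover the window.
#' @export
spatial_bias <- function(cue_profile, sac_profile, rpt_ms,
                         window = c(-50, 0)) {
  grid <- sac_profile$t_ms
  in_win <- grid >= window[1] & grid <= window[2]
  if (!any(in_win) || min(grid) > window[1] || max(grid) < window[2]) {
    warn("Saccade-aligned grid does not cover the presaccadic window.")
    return(NA_real_)
  }
  sup <- superimpose(cue_profile, sac_profile, rpt_ms)
  mean(sup$cue_hz[in_win] - sup$sac_hz[in_win])
}

#' Model bias curve over processing time
#'
#' Evaluates [spatial_bias()] over a grid of rPT values, tracing how the
#' balance between cue-driven and goal-driven presaccadic activity changes
#' with the time separating cue onset from saccade onset.
#'
#' @inheritParams spatial_bias
#' @param rpt_grid_ms rPT grid (ms), default 70–300 by 1.
#' @return A tibble of class `bias_curve` with `rpt_ms` and `bias_hz`.
#' @export
bias_curve <- function(cue_profile, sac_profile,
                       rpt_grid_ms = seq(70, 300, by = 1),
                       window = c(-50, 0)) {
  bias <- vapply(rpt_grid_ms, function(r) {
    spatial_bias(cue_profile, sac_profile, r, window)
  }, numeric(1))
  structure(tibble::tibble(rpt_ms = rpt_grid_ms, bias_hz = bias),
            class = c("bias_curve", class(tibble::tibble())),
            window = window)
}
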