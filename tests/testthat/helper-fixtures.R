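# Fixtures built in code: small deterministic trial tables and hand-made
# spike recordings used across test files.

# trials at fixed rPTs with known outcomes (classification already applied)
fixture_trials <- function(rpt_ms, outcome) {
  tibble::tibble(
    trial_id = seq_along(rpt_ms),
    cue_dir_deg = 180, target_dir_deg = 0,
    saccade_dir_deg = ifelse(outcome == "correct", 0, 180),
    rt_ms = rpt_ms, gap_condition = "zero_gap",
    rpt_ms = rpt_ms, outcome = outcome
  )
}

# one antisaccade trial row with hand-placed spikes (saccade onset at t = 0
# means spike times are already saccade-aligned when saccade_on_ms = 0)
fixture_anti_row <- function(neuron_id, trial_id, condition, rpt_ms, spikes) {
  tibble::tibble(
    neuron_id = neuron_id, trial_id = trial_id, task = "antisaccade",
    outcome = "correct",
    cue_in_rf = condition == "cue_in", saccade_in_rf = condition == "sac_in",
    cue_on_ms = -rpt_ms, go_ms = -rpt_ms, saccade_on_ms = 0,
    rpt_ms = rpt_ms, spike_times_ms = list(spikes)
  )
}

# recording with n_cue cue-in trials of `cue_count` spikes in the presac
# window and n_sac saccade-in trials of `sac_count` spikes
fixture_counts_recording <- function(neuron_id, n_cue, cue_count,
                                     n_sac, sac_count, rpt_ms = 150) {
  mk <- function(k) if (k > 0) seq(-49, -1, length.out = k) else numeric(0)
  rows <- c(
    purrr::map(seq_len(n_cue), function(i) {
      fixture_anti_row(neuron_id, i, "cue_in", rpt_ms, mk(cue_count))
    }),
    purrr::map(seq_len(n_sac), function(i) {
      fixture_anti_row(neuron_id, n_cue + i, "sac_in", rpt_ms, mk(sac_count))
    })
  )
  dplyr::bind_rows(rows)
}

# pooled-counts table in the shape pool_and_center() returns, built directly
fixture_centered <- function(rpt_ms, condition, centered) {
  tibble::tibble(
    neuron_id = "x", trial_id = seq_along(rpt_ms),
    condition = condition, rpt_ms = rpt_ms,
    count = centered, centered = centered
  )
}

# exhaustive pairwise-count ROC oracle (independent of roc_area's ranks)
roc_oracle <- function(a, b) {
  s <- 0
  for (x in a) for (y in b) s <- s + (x > y) + 0.5 * (x == y)
  s / (length(a) * length(b))
}
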