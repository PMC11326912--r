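# Plain-text interchange: trial tables as CSV, spike data as JSON lines.

#' Read and write trial tables
#'
#' Trial tables are exchanged as CSV with columns `trial_id`, `stage`,
#' `gap_condition`, `cue_dir_deg`, `target_dir_deg`, `saccade_dir_deg`,
#' `rt_ms`, `rpt_ms` (extra columns pass through).
#'
#' @param trials A trial tibble.
#' @param path File path.
#' @return `read_trials_csv()` returns a tibble; `write_trials_csv()` the
#'   input, invisibly.
#' @export
write_trials_csv <- function(trials, path) {
  readr::write_csv(trials, path)
  invisible(trials)
}

#' @rdname write_trials_csv
#' @export
read_trials_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Read and write spike recordings as JSON lines
#'
#' One JSON object per line per trial: `neuron_id`, `trial_id`, `task`,
#' `cue_dir_deg`, `rf_dir_deg`, `cue_in_rf`, `saccade_in_rf`, `cue_on_ms`,
#' `go_ms`, `saccade_on_ms`, `rpt_ms`, `outcome`, and the
#' `spike_times_ms` array.
#'
#' @param recording A recording tibble with a `spike_times_ms` list-column.
#' @param path File path.
#' @return `read_spikes_jsonl()` returns a recording tibble;
#'   `write_spikes_jsonl()` the input, invisibly.
#' @export
write_spikes_jsonl <- function(recording, path) {
  stopifnot(is.data.frame(recording), "spike_times_ms" %in% names(recording))
  lines <- purrr::map_chr(seq_len(nrow(recording)), function(i) {
    row <- as.list(recording[i, setdiff(names(recording), "spike_times_ms")])
    row$spike_times_ms <- recording$spike_times_ms[[i]]
    jsonlite::toJSON(row, auto_unbox = TRUE, digits = NA)
  })
  writeLines(lines, path)
  invisible(recording)
}

#' Read and write response profiles
#'
#' A profile is stored as a two-column CSV (`t_ms`, `rate_hz`) with its
#' alignment recorded in a JSON sidecar file (`<path>.json`).
#'
#' @param profile A [response_profile()].
#' @param path CSV file path; the sidecar is written next to it.
#' @return `read_profile_csv()` returns a [response_profile()];
#'   `write_profile_csv()` the input, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "response_profile"))
  readr::write_csv(profile[, c("t_ms", "rate_hz")], path)
  jsonlite::write_json(list(alignment = attr(profile, "alignment")),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(profile)
}

#' @rdname write_profile_csv
#' @export
read_profile_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"))
  response_profile(df$t_ms, df$rate_hz, alignment = side$alignment)
}

#' @rdname write_spikes_jsonl
#' @export
read_spikes_jsonl <- function(path) {
  rows <- purrr::map(readLines(path), function(l) {
    obj <- jsonlite::fromJSON(l)
    spikes <- as.numeric(obj$spike_times_ms)
    obj$spike_times_ms <- NULL
    df <- tibble::as_tibble(obj)
    df$spike_times_ms <- list(spikes)
    df
  })
  dplyr::bind_rows(rows)
}
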