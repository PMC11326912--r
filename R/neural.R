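#' Gaussian-kernel spike density function
#'
#' Converts a spike train into a continuous firing-rate trace by summing a
#' Gaussian kernel (SD `sigma_ms`, default 21 ms) centred at each spike time.
#' The kernel is truncated at `trunc_sd` standard deviations and not
#' renormalized, so each spike contributes unit mass up to a truncation error
#' below 1e-4 and the single-spike peak equals \eqn{1/(\sigma\sqrt{2\pi})}.
#'
#' @param spike_times_ms Numeric vector of spike times (ms), any alignment.
#' @param t_grid_ms Time grid (ms) on which to evaluate the trace.
#' @param sigma_ms Kernel standard deviation (ms).
#' @param trunc_sd Truncation half-width in units of `sigma_ms`.
#' @return A tibble with `t_ms` and `rate_hz` (spikes/s).
#' @export
spike_density <- function(spike_times_ms, t_grid_ms, sigma_ms = 21,
                          trunc_sd = 4) {
  check_number(sigma_ms, "sigma_ms", min = 1e-9)
  rate <- sdf_vector(spike_times_ms, t_grid_ms, sigma_ms, trunc_sd)
  tibble::tibble(t_ms = t_grid_ms, rate_hz = rate)
}

sdf_vector <- function(spikes, grid, sigma_ms, trunc_sd = 4) {
  r <- numeric(length(grid))
  spikes <- spikes[!is.na(spikes)]
  if (length(spikes) == 0) return(r)
  win <- trunc_sd * sigma_ms
  for (s in spikes) {
    idx <- which(abs(grid - s) <= win)
    if (length(idx) > 0) {
      r[idx] <- r[idx] + dnorm(grid[idx], s, sigma_ms)
    }
  }
  r * 1000  # per-ms density -> spikes/s
}

#' Population-average spike density
#'
#' Builds the per-neuron trial-averaged spike density aligned to a task
#' event, then averages across neurons; the error band is the across-neuron
#' standard error of the mean at each time point. With a single neuron the
#' mean is returned and the SEM is `NA`.
#'
#' @param recording A trial table with `neuron_id`, a `spike_times_ms`
#'   list-column, and the alignment event column.
#' @param align Event column to align to (e.g. `"cue_on_ms"`,
#'   `"saccade_on_ms"`). Trials with a missing event are skipped with a
#'   warning.
#' @param t_grid_ms Time grid relative to the event (ms).
#' @inheritParams spike_density
#' @return A tibble with `t_ms`, `mean_hz`, `sem_hz`, `n_neurons`.
#' @export
population_average <- function(recording, align = "cue_on_ms",
                               t_grid_ms = seq(-500, 500, by = 5),
                               sigma_ms = 21, trunc_sd = 4) {
  stopifnot(is.data.frame(recording),
            all(c("neuron_id", "spike_times_ms") %in% names(recording)))
  if (!align %in% names(recording)) {
    abort(sprintf("Alignment event column `%s` not found.", align))
  }
  miss <- is.na(recording[[align]])
  if (any(miss)) {
    warn(sprintf("Skipping %d trial(s) with missing `%s`.", sum(miss), align))
    recording <- recording[!miss, ]
  }
  per_neuron <- recording |>
    dplyr::group_by(.data$neuron_id) |>
    dplyr::group_map(function(df, key) {
      traces <- vapply(seq_len(nrow(df)), function(i) {
        sdf_vector(df$spike_times_ms[[i]] - df[[align]][i], t_grid_ms,
                   sigma_ms, trunc_sd)
      }, numeric(length(t_grid_ms)))
      rowMeans(traces)
    })
  m <- do.call(cbind, per_neuron)
  k <- ncol(m)
  tibble::tibble(
    t_ms = t_grid_ms,
    mean_hz = rowMeans(m),
    sem_hz = if (k >= 2) apply(m, 1, sd) / sqrt(k) else NA_real_,
    n_neurons = k
  )
}

#' Firing rate in a time window
#'
#' Spike count in the half-open window `[start, end)` divided by the window
#' duration, in spikes/s.
#'
#' @param spike_times_ms Spike times (ms), same alignment as the window.
#' @param window_ms Length-2 numeric `c(start, end)` in ms.
#' @return Rate in spikes/s.
#' @export
window_rate <- function(spike_times_ms, window_ms) {
  if (length(window_ms) != 2 || diff(window_ms) <= 0) {
    abort("`window_ms` must be an increasing c(start, end) pair.")
  }
  n <- sum(spike_times_ms >= window_ms[1] & spike_times_ms < window_ms[2])
  n / (diff(window_ms) / 1000)
}

window_count <- function(spike_times_ms, window_ms) {
  sum(spike_times_ms >= window_ms[1] & spike_times_ms < window_ms[2])
}

# one-sided (greater) paired t-test p-value on per-trial rate differences
paired_elevation_p <- function(a, b) {
  d <- a - b
  if (length(d) < 2) return(NA_real_)
  if (sd(d) == 0) return(if (mean(d) > 0) 0 else 1)
  t.test(a, b, paired = TRUE, alternative = "greater")$p.value
}

#' Classify a neuron as visual / presaccadic / visuomotor
#'
#' Applies the three selection criteria for visuomotor (VM) neurons, each a
#' one-sided paired t-test for rate elevation at `p < alpha`:
#' \itemize{
#'   \item visual: mean rate during the 500-ms cue presentation of the
#'     memory-guided (ODR) task exceeds the preceding 1000-ms fixation rate
#'     at one or more cue locations; the response field (RF) is the location
#'     with the largest significant elevation;
#'   \item presaccadic: mean rate in the 250-ms window after the go signal
#'     exceeds the fixation rate at one or more locations;
#'   \item consistent: in the antisaccade task, the rate in the 250-ms window
#'     after cue onset with the cue in the RF exceeds the fixation rate.
#' }
#' `is_vm` requires all three. Locations with fewer than 2 trials are
#' excluded from testing.
#'
#' @param recording Trial table for one neuron holding both tasks (column
#'   `task` in `{"odr", "antisaccade"}`) with `cue_dir_deg`, `cue_on_ms`,
#'   `go_ms` and `spike_times_ms`.
#' @param alpha Significance level per test (default 0.05).
#' @return A one-row tibble: `neuron_id`, `visual`, `presaccadic`,
#'   `consistent`, `is_vm`, `rf_dir_deg` (NA when not visual).
#' @export
classify_neuron <- function(recording, alpha = 0.05) {
  stopifnot(is.data.frame(recording))
  odr <- dplyr::filter(recording, .data$task == "odr")
  anti <- dplyr::filter(recording, .data$task == "antisaccade")
  if (nrow(odr) == 0 || nrow(anti) == 0) {
    abort("`recording` must contain both ODR and antisaccade trials.")
  }
  rate_rel <- function(df, event, w) {
    vapply(seq_len(nrow(df)), function(i) {
      window_rate(df$spike_times_ms[[i]] - df[[event]][i], w)
    }, numeric(1))
  }
  odr_stats <- odr |>
    dplyr::mutate(
      fix_hz = rate_rel(odr, "cue_on_ms", c(-1000, 0)),
      cue_hz = rate_rel(odr, "cue_on_ms", c(0, 500)),
      go_hz = rate_rel(odr, "go_ms", c(0, 250))
    ) |>
    dplyr::group_by(.data$cue_dir_deg) |>
    dplyr::filter(dplyr::n() >= 2) |>
    dplyr::summarise(
      p_vis = paired_elevation_p(.data$cue_hz, .data$fix_hz),
      elev = mean(.data$cue_hz - .data$fix_hz),
      p_sac = paired_elevation_p(.data$go_hz, .data$fix_hz),
      .groups = "drop"
    )
  vis_sig <- !is.na(odr_stats$p_vis) & odr_stats$p_vis < alpha
  visual <- any(vis_sig)
  rf <- if (visual) {
    odr_stats$cue_dir_deg[vis_sig][which.max(odr_stats$elev[vis_sig])]
  } else NA_real_
  presaccadic <- any(!is.na(odr_stats$p_sac) & odr_stats$p_sac < alpha)
  consistent <- FALSE
  if (visual) {
    arf <- dplyr::filter(anti, circ_dist(.data$cue_dir_deg, rf) < 22.5)
    if (nrow(arf) >= 2) {
      fix <- rate_rel(arf, "cue_on_ms", c(-1000, 0))
      cue <- rate_rel(arf, "cue_on_ms", c(0, 250))
      p <- paired_elevation_p(cue, fix)
      consistent <- !is.na(p) && p < alpha
    }
  }
  tibble::tibble(
    neuron_id = recording$neuron_id[1],
    visual = visual, presaccadic = presaccadic, consistent = consistent,
    is_vm = visual && presaccadic && consistent,
    rf_dir_deg = rf
  )
}

#' Cue-window minus presaccadic-window rate differential
#'
#' For each neuron's in-RF memory-guided (ODR) trials, computes the per-trial
#' firing rate 50–150 ms after cue onset and −100–0 ms before saccade onset,
#' and averages their difference. Returns per-neuron differentials, per-group
#' mean ± SEM, and — when exactly two groups with at least two neurons each
#' are present — the two-sided unpaired randomization-test p-value for the
#' group contrast.
#'
#' @param recordings Trial table across neurons (`neuron_id`, optional
#'   `group` column, `cue_in_rf`, `task`, event times, spikes).
#' @param cue_window Window after cue onset (ms), default `c(50, 150)`.
#' @param sac_window Window around saccade onset (ms), default `c(-100, 0)`.
#' @param group Name of the grouping column (e.g. stage); optional.
#' @param n_perm Randomization draws for the contrast.
#' @param seed Seed for the randomization test.
#' @return A list with `neurons` (tibble: `neuron_id`, group, `delta_hz`,
#'   `n_trials`), `summary` (per-group mean, SEM, n), and `contrast`
#'   (randomization-test tibble or `NULL`).
#' @export
cue_saccade_differential <- function(recordings, cue_window = c(50, 150),
                                     sac_window = c(-100, 0), group = NULL,
                                     n_perm = 10000, seed = 1) {
  stopifnot(is.data.frame(recordings))
  df <- dplyr::filter(recordings, .data$task == "odr", .data$cue_in_rf)
  if (nrow(df) == 0) abort("No in-RF ODR trials found.")
  keys <- c("neuron_id", group)
  neurons <- df |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::group_modify(function(d, key) {
      cue_hz <- vapply(seq_len(nrow(d)), function(i) {
        window_rate(d$spike_times_ms[[i]] - d$cue_on_ms[i], cue_window)
      }, numeric(1))
      sac_hz <- vapply(seq_len(nrow(d)), function(i) {
        window_rate(d$spike_times_ms[[i]] - d$saccade_on_ms[i], sac_window)
      }, numeric(1))
      tibble::tibble(delta_hz = mean(cue_hz - sac_hz), n_trials = nrow(d))
    }) |>
    dplyr::ungroup()
  grp_col <- if (is.null(group)) rep("all", nrow(neurons)) else neurons[[group]]
  summary <- neurons |>
    dplyr::group_by(group = grp_col) |>
    dplyr::summarise(
      mean_delta_hz = mean(.data$delta_hz),
      sem_delta_hz = if (dplyr::n() >= 2) sd(.data$delta_hz) / sqrt(dplyr::n())
                     else NA_real_,
      n_neurons = dplyr::n(), .groups = "drop"
    )
  contrast <- NULL
  groups <- unique(grp_col)
  if (length(groups) == 2) {
    a <- neurons$delta_hz[grp_col == groups[1]]
    b <- neurons$delta_hz[grp_col == groups[2]]
    if (length(a) >= 2 && length(b) >= 2) {
      contrast <- permutation_test(a, b, paired = FALSE,
                                   alternative = "two.sided",
                                   n_perm = n_perm, seed = seed)
    }
  }
  list(neurons = neurons, summary = summary, contrast = contrast)
}

#' ROC area between two spike-count samples
#'
#' The probability that a randomly drawn cue-in count exceeds a randomly
#' drawn saccade-in count, with ties credited one half (the Mann–Whitney
#' identity). Values above 0.5 indicate cue-dominant activity; 0.5 means the
#' two distributions are indistinguishable; 0 or 1 means fully separable.
#'
#' @param counts_cue_in,counts_sac_in Numeric samples (spike counts, possibly
#'   centered and hence non-integer).
#' @return The ROC area in `[0, 1]`, or `NA_real_` if either sample is empty.
#' @examples
#' roc_area(c(5, 6, 7), c(1, 2, 3))  # 1: fully separated, cue-dominant
#' @export
roc_area <- function(counts_cue_in, counts_sac_in) {
  n <- length(counts_cue_in); m <- length(counts_sac_in)
  if (n == 0 || m == 0) return(NA_real_)
  r <- rank(c(counts_cue_in, counts_sac_in))
  (sum(r[seq_len(n)]) - n * (n + 1) / 2) / (n * m)
}

#' Pool presaccadic spike counts across neurons with per-neuron centering
#'
#' For correct antisaccade trials in which exactly one of the two RF labels
#' is active, counts spikes in the presaccadic window (default −50 to 0 ms,
#' aligned on saccade onset) and centers each neuron's counts by its constant
#' \eqn{\theta = (\mu_{cue} + \mu_{sac})/2}, the midpoint of its mean
#' cue-in and saccade-in counts. Centering this way removes overall rate
#' differences between neurons while remaining insensitive to unequal trial
#' counts in the two conditions. Neurons observed in only one condition are
#' excluded and reported in the diagnostics.
#'
#' @param recordings Trial table across neurons (`neuron_id`, `task`,
#'   `outcome`, `cue_in_rf`, `saccade_in_rf`, `saccade_on_ms`, `rpt_ms`,
#'   `spike_times_ms`).
#' @param presac_window Counting window relative to saccade onset (ms).
#' @return A tibble of class `centered_counts`: `neuron_id`, `trial_id`,
#'   `condition` (`"cue_in"`/`"sac_in"`), `rpt_ms`, `count`, `centered`; with
#'   attributes `thetas` (per-neuron `mu_cue`, `mu_sac`, `theta`) and
#'   `excluded` (neuron ids dropped).
#' @export
pool_and_center <- function(recordings, presac_window = c(-50, 0)) {
  stopifnot(is.data.frame(recordings))
  df <- recordings
  if ("task" %in% names(df)) df <- dplyr::filter(df, .data$task == "antisaccade")
  if ("outcome" %in% names(df)) df <- dplyr::filter(df, .data$outcome == "correct")
  df <- dplyr::filter(df, xor(.data$cue_in_rf, .data$saccade_in_rf))
  if (nrow(df) == 0) abort("No correct antisaccade trials with an active RF label.")
  counts <- vapply(seq_len(nrow(df)), function(i) {
    window_count(df$spike_times_ms[[i]] - df$saccade_on_ms[i], presac_window)
  }, numeric(1))
  df <- df |>
    dplyr::mutate(condition = ifelse(.data$cue_in_rf, "cue_in", "sac_in"),
                  count = counts)
  thetas <- df |>
    dplyr::group_by(.data$neuron_id) |>
    dplyr::summarise(
      mu_cue = mean(.data$count[.data$condition == "cue_in"]),
      mu_sac = mean(.data$count[.data$condition == "sac_in"]),
      .groups = "drop"
    ) |>
    dplyr::mutate(theta = (.data$mu_cue + .data$mu_sac) / 2)
  excluded <- thetas$neuron_id[is.na(thetas$theta)]
  thetas <- dplyr::filter(thetas, !is.na(.data$theta))
  out <- df |>
    dplyr::inner_join(thetas[, c("neuron_id", "theta")], by = "neuron_id") |>
    dplyr::mutate(centered = .data$count - .data$theta) |>
    dplyr::select(dplyr::all_of(c("neuron_id", "trial_id", "condition",
                                  "rpt_ms", "count", "centered")))
  structure(out, class = c("centered_counts", class(tibble::tibble())),
            thetas = thetas, excluded = excluded,
            presac_window = presac_window)
}

# s_roc replicates from resampling the two groups with replacement
sroc_boot_reps <- function(cue, sac, n_boot) {
  n <- length(cue); m <- length(sac)
  vapply(seq_len(n_boot), function(i) {
    roc_area(cue[sample.int(n, n, replace = TRUE)],
             sac[sample.int(m, m, replace = TRUE)])
  }, numeric(1))
}

#' Bootstrap confidence bands for an ROC spatial signal
#'
#' Resamples the cue-in and saccade-in count distributions with replacement
#' (default 1000 iterations) and recomputes the ROC area each time;
#' percentile intervals give 68% and 95% bands. Deterministic given the seed.
#'
#' @inheritParams roc_area
#' @param n_boot Number of resampling iterations.
#' @param seed Integer seed.
#' @return A list: `s_roc` (point estimate), `replicates`, `ci68`, `ci95`.
#' @export
bootstrap_sroc <- function(counts_cue_in, counts_sac_in, n_boot = 1000,
                           seed = 1) {
  point <- roc_area(counts_cue_in, counts_sac_in)
  reps <- withr::with_seed(seed, {
    sroc_boot_reps(counts_cue_in, counts_sac_in, n_boot)
  })
  list(
    s_roc = point, replicates = reps,
    ci68 = as.numeric(quantile(reps, c(0.16, 0.84), na.rm = TRUE)),
    ci95 = as.numeric(quantile(reps, c(0.025, 0.975), na.rm = TRUE))
  )
}

#' Neurometric curve: pooled ROC signal over processing time
#'
#' Computes the spatial signal S_ROC — the ROC area between pooled centered
#' presaccadic spike counts for cue-in versus saccade-in trials — within
#' running rPT bins (default 80 ms wide, shifted every 1 ms). Bins holding
#' fewer than `min_n` pooled trials are flagged with `NA`. Optional bootstrap
#' bands (68%/95%) are computed per bin by resampling the two groups.
#'
#' @param centered A [pool_and_center()] result.
#' @param bin_width_ms Bin width (ms), default 80.
#' @param step_ms Bin step (ms), default 1.
#' @param rpt_range Range of bin centers (ms), default `c(70, 300)`.
#' @param min_n Minimum pooled trials per bin.
#' @param n_boot Bootstrap iterations per bin (0 = no bands).
#' @param seed Integer seed for the bootstrap.
#' @return A tibble of class `neurometric_curve`: `rpt_ms`, `s_roc`,
#'   `n_cue`, `n_sac`, `n`, and (with `n_boot > 0`) `ci68_low`, `ci68_high`,
#'   `ci95_low`, `ci95_high`.
#' @export
neurometric_curve <- function(centered, bin_width_ms = 80, step_ms = 1,
                              rpt_range = c(70, 300), min_n = 20,
                              n_boot = 0, seed = 1) {
  stopifnot(is.data.frame(centered),
            all(c("condition", "rpt_ms", "centered") %in% names(centered)))
  centers <- seq(rpt_range[1], rpt_range[2], by = step_ms)
  hw <- bin_width_ms / 2
  ord <- order(centered$rpt_ms)
  rpt <- centered$rpt_ms[ord]
  val <- centered$centered[ord]
  is_cue <- centered$condition[ord] == "cue_in"
  lo_i <- findInterval(centers - hw, rpt, left.open = TRUE)
  hi_i <- findInterval(centers + hw, rpt, left.open = TRUE)
  one_bin <- function(j) {
    if (hi_i[j] <= lo_i[j]) return(NULL)
    idx <- (lo_i[j] + 1):hi_i[j]
    list(cue = val[idx][is_cue[idx]], sac = val[idx][!is_cue[idx]])
  }
  rows <- withr::with_seed(seed, {
    purrr::map(seq_along(centers), function(j) {
      g <- one_bin(j)
      n_cue <- length(g$cue); n_sac <- length(g$sac)
      ok <- !is.null(g) && n_cue > 0 && n_sac > 0 &&
        (n_cue + n_sac) >= min_n
      row <- tibble::tibble(
        rpt_ms = centers[j],
        s_roc = if (ok) roc_area(g$cue, g$sac) else NA_real_,
        n_cue = n_cue, n_sac = n_sac, n = n_cue + n_sac
      )
      if (n_boot > 0) {
        if (ok) {
          reps <- sroc_boot_reps(g$cue, g$sac, n_boot)
          q <- quantile(reps, c(0.16, 0.84, 0.025, 0.975), na.rm = TRUE)
        } else {
          q <- rep(NA_real_, 4)
        }
        row$ci68_low <- q[1]; row$ci68_high <- q[2]
        row$ci95_low <- q[3]; row$ci95_high <- q[4]
      }
      row
    })
  })
  structure(dplyr::bind_rows(rows),
            class = c("neurometric_curve", class(tibble::tibble())),
            bin_width_ms = bin_width_ms, min_n = min_n, n_boot = n_boot)
}

#' Pooled ROC signal in short and long rPT ranges
#'
#' One pooled S_ROC per rPT range — short (70 ≤ rPT < 170 ms, where capture
#' dominates) and long (170 ≤ rPT ≤ 300 ms, where correct choices dominate)
#' by default — with bootstrap confidence intervals and a two-sided
#' resampling test of their difference.
#'
#' @inheritParams neurometric_curve
#' @param short,long Range bounds in ms; the short range is half-open on the
#'   right, the long range closed.
#' @param n_boot Bootstrap iterations.
#' @return A list with `by_range` (tibble: range, s_roc, n per condition,
#'   CI bounds) and `difference` (tibble: estimate and two-sided bootstrap
#'   p-value).
#' @export
sroc_binned <- function(centered, short = c(70, 170), long = c(170, 300),
                        n_boot = 1000, seed = 1) {
  stopifnot(is.data.frame(centered))
  pick <- function(lo, hi, closed_right) {
    inside <- centered$rpt_ms >= lo &
      (if (closed_right) centered$rpt_ms <= hi else centered$rpt_ms < hi)
    centered[inside, ]
  }
  groups <- list(short = pick(short[1], short[2], FALSE),
                 long = pick(long[1], long[2], TRUE))
  res <- withr::with_seed(seed, {
    purrr::imap(groups, function(g, nm) {
      cue <- g$centered[g$condition == "cue_in"]
      sac <- g$centered[g$condition == "sac_in"]
      if (length(cue) == 0 || length(sac) == 0) {
        return(list(row = tibble::tibble(
          range = nm, s_roc = NA_real_, n_cue = length(cue),
          n_sac = length(sac), ci68_low = NA_real_, ci68_high = NA_real_,
          ci95_low = NA_real_, ci95_high = NA_real_), reps = NULL))
      }
      reps <- sroc_boot_reps(cue, sac, n_boot)
      q <- quantile(reps, c(0.16, 0.84, 0.025, 0.975), na.rm = TRUE)
      list(row = tibble::tibble(
        range = nm, s_roc = roc_area(cue, sac), n_cue = length(cue),
        n_sac = length(sac), ci68_low = q[1], ci68_high = q[2],
        ci95_low = q[3], ci95_high = q[4]), reps = reps)
    })
  })
  by_range <- dplyr::bind_rows(purrr::map(res, "row"))
  difference <- NULL
  if (!is.null(res$short$reps) && !is.null(res$long$reps)) {
    d <- res$short$reps - res$long$reps
    p <- 2 * min(mean(d <= 0), mean(d >= 0))
    difference <- tibble::tibble(
      estimate = by_range$s_roc[1] - by_range$s_roc[2],
      p_value = min(1, max(p, 1 / (n_boot + 1)))
    )
  }
  list(by_range = by_range, difference = difference)
}

#' Permutation and randomization tests
#'
#' Tests a difference in means by permuting group labels (unpaired,
#' "randomization test") or by flipping the signs of paired differences
#' (paired, "permutation test"). When the number of distinct rearrangements
#' is at most `exhaustive_cap`, all are enumerated and the p-value is the
#' exact fraction of rearranged statistics at least as extreme as the
#' observed one; otherwise `n_perm` Monte-Carlo draws are used with the
#' add-one correction, so p is always in (0, 1].
#'
#' @param a,b Numeric samples; for `paired = TRUE` they must have equal
#'   length.
#' @param paired Paired (sign-flip) or unpaired (label-shuffle) test.
#' @param alternative `"two.sided"`, `"greater"` (a > b), or `"less"`.
#' @param n_perm Monte-Carlo draws when enumeration is infeasible.
#' @param exhaustive_cap Maximum number of rearrangements to enumerate.
#' @param seed Integer seed for the Monte-Carlo branch.
#' @return A one-row tibble: `statistic` (observed mean difference),
#'   `p_value`, `method`, `exact`, `n_used`.
#' @examples
#' permutation_test(c(1, 2), c(3, 4))  # exhaustive: p = 1/3
#' @export
permutation_test <- function(a, b, paired = FALSE,
                             alternative = c("two.sided", "greater", "less"),
                             n_perm = 10000, exhaustive_cap = 20000,
                             seed = 1) {
  alternative <- match.arg(alternative)
  if (length(a) == 0 || length(b) == 0) abort("Samples must be non-empty.")
  if (paired && length(a) != length(b)) {
    abort("Paired samples must have equal lengths.")
  }
  eps <- 1e-12
  tail_p <- function(perm, obs) {
    switch(alternative,
           two.sided = mean(abs(perm) >= abs(obs) - eps),
           greater = mean(perm >= obs - eps),
           less = mean(perm <= obs + eps))
  }
  if (paired) {
    d <- a - b
    obs <- mean(d)
    n <- length(d)
    if (2^n <= exhaustive_cap) {
      signs <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
      perm <- as.numeric(signs %*% d) / n
      p <- tail_p(perm, obs)
      exact <- TRUE; n_used <- nrow(signs)
    } else {
      perm <- withr::with_seed(seed, {
        vapply(seq_len(n_perm), function(i) {
          mean(d * sample(c(-1, 1), n, replace = TRUE))
        }, numeric(1))
      })
      k <- switch(alternative,
                  two.sided = sum(abs(perm) >= abs(obs) - eps),
                  greater = sum(perm >= obs - eps),
                  less = sum(perm <= obs + eps))
      p <- (k + 1) / (n_perm + 1)
      exact <- FALSE; n_used <- n_perm
    }
    method <- "paired permutation (sign flip)"
  } else {
    obs <- mean(a) - mean(b)
    pool <- c(a, b)
    n <- length(pool); na <- length(a)
    n_comb <- choose(n, na)
    if (n_comb <= exhaustive_cap) {
      idx <- utils::combn(n, na)
      tot <- sum(pool)
      perm <- apply(idx, 2, function(ii) {
        sa <- sum(pool[ii])
        sa / na - (tot - sa) / (n - na)
      })
      p <- tail_p(perm, obs)
      exact <- TRUE; n_used <- n_comb
    } else {
      tot <- sum(pool)
      perm <- withr::with_seed(seed, {
        vapply(seq_len(n_perm), function(i) {
          ii <- sample.int(n, na)
          sa <- sum(pool[ii])
          sa / na - (tot - sa) / (n - na)
        }, numeric(1))
      })
      k <- switch(alternative,
                  two.sided = sum(abs(perm) >= abs(obs) - eps),
                  greater = sum(perm >= obs - eps),
                  less = sum(perm <= obs + eps))
      p <- (k + 1) / (n_perm + 1)
      exact <- FALSE; n_used <- n_perm
    }
    method <- "unpaired randomization (label shuffle)"
  }
  tibble::tibble(statistic = obs, p_value = p, method = method,
                 exact = exact, n_used = n_used)
}
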