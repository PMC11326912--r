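#' Raw processing time from reaction time
#'
#' The raw processing time (rPT) is the interval between cue onset and saccade
#' onset: the time available to view and process the cue before committing to
#' a movement. It follows from the reaction time (RT, go signal to saccade
#' onset) and the timing variant: in the overlap condition the cue leads the
#' go signal by 100 ms (rPT = RT + 100); with zero gap they coincide
#' (rPT = RT); in the gap conditions the cue lags by the blank duration
#' (rPT = RT − 100 or RT − 200).
#'
#' @param trials A data frame with columns `rt_ms` and `gap_condition`
#'   (`"overlap"`, `"zero_gap"`, `"gap100"`, `"gap200"`).
#' @return The input as a tibble with an `rpt_ms` column added (replaced if
#'   already present).
#' @examples
#' compute_rpt(tibble::tibble(rt_ms = c(250, 180, 220),
#'                            gap_condition = c("overlap", "zero_gap", "gap100")))
#' @export
compute_rpt <- function(trials) {
  stopifnot(is.data.frame(trials))
  if (!all(c("rt_ms", "gap_condition") %in% names(trials))) {
    abort("`trials` must have columns `rt_ms` and `gap_condition`.")
  }
  dplyr::mutate(tibble::as_tibble(trials),
                rpt_ms = .data$rt_ms + rpt_offset_ms(.data$gap_condition))
}

#' @rdname compute_rpt
#' @param gap_condition Character vector of timing-variant labels.
#' @return `rpt_offset_ms()` returns the cue-onset offset added to RT.
#' @export
rpt_offset_ms <- function(gap_condition) {
  offsets <- c(overlap = 100, zero_gap = 0, gap100 = -100, gap200 = -200)
  bad <- setdiff(unique(gap_condition), names(offsets))
  if (length(bad) > 0) {
    abort(paste0("Unknown gap condition label(s): ",
                 paste(bad, collapse = ", ")))
  }
  unname(offsets[gap_condition])
}

#' Classify saccades against target and cue windows
#'
#' A saccade is correct if its direction lands within half the spatial window
#' of the target direction, an error (capture) if within half the window of
#' the cue direction, and intermediate otherwise. Distances are circular
#' (wrapped at ±180°) and the bound is inclusive. Trials with a missing
#' saccade direction are labelled `unclassified`.
#'
#' @param trials Data frame with `saccade_dir_deg`, `target_dir_deg`,
#'   `cue_dir_deg` (degrees).
#' @param window_deg Full width of the spatial window, in (0, 180]
#'   (default 90, i.e. ±45°).
#' @return The trials as a tibble with an `outcome` column
#'   (`correct` / `error` / `intermediate` / `unclassified`).
#' @export
classify_saccade <- function(trials, window_deg = 90) {
  stopifnot(is.data.frame(trials))
  if (!is.numeric(window_deg) || window_deg <= 0 || window_deg > 180) {
    abort("`window_deg` must be in (0, 180].")
  }
  need <- c("saccade_dir_deg", "target_dir_deg", "cue_dir_deg")
  if (!all(need %in% names(trials))) {
    abort(paste0("`trials` must have columns: ", paste(need, collapse = ", ")))
  }
  half <- window_deg / 2
  d_target <- circ_dist(trials$saccade_dir_deg, trials$target_dir_deg)
  d_cue <- circ_dist(trials$saccade_dir_deg, trials$cue_dir_deg)
  outcome <- dplyr::case_when(
    is.na(d_target) | is.na(d_cue) ~ "unclassified",
    d_target <= half ~ "correct",
    d_cue <= half ~ "error",
    TRUE ~ "intermediate"
  )
  dplyr::mutate(tibble::as_tibble(trials), outcome = outcome)
}

# Correct/error counts of classified trials in running rPT bins.
# rpt, correct: vectors over valid (correct or error) trials only.
bin_valid_trials <- function(rpt, correct, centers, bin_width_ms) {
  hw <- bin_width_ms / 2
  rc <- sort(rpt[correct])
  re <- sort(rpt[!correct])
  n_correct <- count_in_windows(rc, centers - hw, centers + hw)
  n_error <- count_in_windows(re, centers - hw, centers + hw)
  list(n_correct = n_correct, n_error = n_error)
}

#' Tachometric curve
#'
#' Proportion of correct responses in running rPT bins (bins of
#' `bin_width_ms`, shifted every `step_ms`), with binomial (Wilson score)
#' confidence intervals. Intermediate and unclassified trials are excluded
#' from both numerator and denominator. Bins holding fewer than `min_valid`
#' valid trials are flagged `empty` with `NA` proportions.
#'
#' @param trials Classified trials (see [classify_saccade()]) with `rpt_ms`
#'   and `outcome` columns.
#' @param bin_width_ms Bin width in ms (default 20; 40 is typical for
#'   single-subject curves).
#' @param step_ms Bin step in ms (default 1).
#' @param min_valid Minimum valid trials for a bin to be reported.
#' @param conf Confidence level for the per-bin binomial interval.
#' @param rpt_range Optional c(min, max) of bin centers; defaults to the span
#'   of the observed rPTs.
#' @return A tibble of class `tachometric_curve` with columns
#'   `bin_center_ms`, `n_correct`, `n_error`, `n_valid`, `prop_correct`,
#'   `ci_low`, `ci_high`, `empty`. Zero valid trials give a zero-row curve.
#' @export
tachometric_curve <- function(trials, bin_width_ms = 20, step_ms = 1,
                              min_valid = 1, conf = 0.95, rpt_range = NULL) {
  stopifnot(is.data.frame(trials))
  if (!all(c("rpt_ms", "outcome") %in% names(trials))) {
    abort("`trials` must have `rpt_ms` and `outcome` columns; run compute_rpt() and classify_saccade() first.")
  }
  valid <- trials$outcome %in% c("correct", "error")
  rpt <- trials$rpt_ms[valid]
  correct <- trials$outcome[valid] == "correct"
  new_curve <- function(df) {
    structure(df, class = c("tachometric_curve", class(tibble::tibble())),
              bin_width_ms = bin_width_ms, step_ms = step_ms, conf = conf)
  }
  if (length(rpt) == 0) {
    return(new_curve(tibble::tibble(
      bin_center_ms = numeric(), n_correct = integer(), n_error = integer(),
      n_valid = integer(), prop_correct = numeric(), ci_low = numeric(),
      ci_high = numeric(), empty = logical()
    )))
  }
  if (is.null(rpt_range)) rpt_range <- c(floor(min(rpt)), ceiling(max(rpt)))
  centers <- seq(rpt_range[1], rpt_range[2], by = step_ms)
  cnt <- bin_valid_trials(rpt, correct, centers, bin_width_ms)
  n_valid <- cnt$n_correct + cnt$n_error
  prop <- ifelse(n_valid > 0, cnt$n_correct / n_valid, NA_real_)
  ci <- wilson_ci(cnt$n_correct, n_valid, conf)
  empty <- n_valid < min_valid
  prop[empty] <- NA_real_
  ci$low[empty] <- NA_real_
  ci$high[empty] <- NA_real_
  new_curve(tibble::tibble(
    bin_center_ms = centers,
    n_correct = cnt$n_correct, n_error = cnt$n_error, n_valid = n_valid,
    prop_correct = prop, ci_low = ci$low, ci_high = ci$high, empty = empty
  ))
}

# data-driven starting values for the six free parameters
fit_starts <- function(x, y, al) {
  b0 <- max(min(y), 0.01)
  ar0 <- min(max(stats::quantile(y, 0.95), al + 0.01), 0.99)
  i_min <- which.min(y)
  x_min <- x[i_min]
  # half-crossing estimates on either side of the minimum
  left <- which(x <= x_min & y <= (al + b0) / 2)
  cl0 <- if (length(left) > 0) x[left[1]] else x_min - 20
  right <- which(x >= x_min & y >= (b0 + ar0) / 2)
  cr0 <- if (length(right) > 0) x[right[1]] else x_min + 30
  c(b0, ar0, cl0, 10, cr0, 10)
}

fit_bounds <- function(x, al) {
  lo <- c(0, al, min(x) - 50, 1, min(x) - 50, 1)
  hi <- c(al, 1, max(x) + 50, 100, max(x) + 50, 100)
  list(lo = lo, hi = hi)
}

# Core MAE fit on binned proportions. start_par, if given, is used as the
# single start (bootstrap refits); otherwise a multi-start strategy is used.
# half_bin > 0 makes the objective compare each binned proportion with the
# model averaged over that bin, removing the smoothing bias of running bins.
fit_sigmoid_core <- function(x, y, al = 0.5, start_par = NULL, maxit = 2000,
                             half_bin = 0) {
  bounds <- fit_bounds(x, al)
  clamp <- function(p) pmin(pmax(p, bounds$lo + 1e-9), bounds$hi - 1e-9)
  starts <- if (!is.null(start_par)) {
    list(clamp(start_par))
  } else {
    s0 <- fit_starts(x, y, al)
    span <- diff(range(x))
    list(
      s0,
      clamp(s0 + c(0.1, -0.05, -0.15 * span, 5, 0.15 * span, 5)),
      clamp(s0 + c(-0.05, 0.04, 0.1 * span, -5, -0.1 * span, -5)),
      clamp(c(0.25, 0.9, min(x) + 0.25 * span, 10, min(x) + 0.5 * span, 10)),
      clamp(c(0.45, 0.75, min(x) + 0.1 * span, 30, min(x) + 0.7 * span, 30))
    )
  }
  if (!is.null(start_par)) {
    # warm start (bootstrap refits): a single simplex run suffices
    return(fit_sigmoid_nm(starts[[1]], bounds$lo, bounds$hi, x, y, al,
                          maxit, 1e-7, half_bin))
  }
  best <- NULL
  for (s in starts) {
    res <- fit_sigmoid_nm(s, bounds$lo, bounds$hi, x, y, al, maxit, 1e-10,
                          half_bin)
    if (is.null(best) || res$value < best$value) best <- res
  }
  # polish from the best solution
  res <- fit_sigmoid_nm(best$par, bounds$lo, bounds$hi, x, y, al, maxit,
                        1e-12, half_bin)
  if (res$value <= best$value) best <- res
  best
}

#' Fit the two-sigmoid model to a tachometric curve
#'
#' Minimises the mean absolute error (MAE) between the binned proportions
#' correct and the model \eqn{v(x) = \max(L(x), R(x), 0)}, with the chance
#' level fixed at `AL = 0.5`. Because a running-bin proportion estimates the
#' average of the true curve over the bin — not its value at the center — the
#' objective compares each proportion with the model averaged over that bin
#' (3-point Gauss quadrature), which removes the finite-bin-width smoothing
#' bias in the recovered midpoints and slopes. The six free parameters
#' (B, AR, CL, DL, CR, DR) are optimised by a Nelder–Mead simplex over
#' box-transformed coordinates (B in \[0, 0.5\], AR in \[0.5, 1\], midpoints
#' within the data range, slopes in \[1, 100\] ms), with several deterministic
#' starts seeded from data-driven heuristics.
#'
#' @param x Either classified trials (with `rpt_ms`, `outcome`) or a
#'   [tachometric_curve()].
#' @inheritParams tachometric_curve
#' @param min_valid Bins with fewer valid trials are excluded from the fit
#'   (default 10).
#' @param start Optional parameter vector c(b, ar, cl, dl, cr, dr) used as the
#'   single start (used internally by the bootstrap).
#' @return A [sigmoid_fit()] with `mae`, `converged`, `n_bins` diagnostics.
#' @export
fit_tachometric <- function(x, bin_width_ms = 20, step_ms = 1, min_valid = 10,
                            start = NULL) {
  if (inherits(x, "tachometric_curve")) {
    curve <- x
    hb <- (attr(curve, "bin_width_ms") %||% bin_width_ms) / 2
    keep <- !curve$empty & curve$n_valid >= min_valid
    xs <- curve$bin_center_ms[keep]
    ys <- curve$prop_correct[keep]
  } else if (is.data.frame(x) && all(c("rpt_ms", "outcome") %in% names(x))) {
    curve <- tachometric_curve(x, bin_width_ms = bin_width_ms,
                               step_ms = step_ms, min_valid = min_valid)
    hb <- bin_width_ms / 2
    keep <- !curve$empty & curve$n_valid >= min_valid
    xs <- curve$bin_center_ms[keep]
    ys <- curve$prop_correct[keep]
  } else if (is.data.frame(x) &&
             all(c("bin_center_ms", "prop_correct") %in% names(x))) {
    # pointwise samples of a curve (no binning): fit values directly
    hb <- 0
    keep <- !is.na(x$prop_correct)
    xs <- x$bin_center_ms[keep]
    ys <- x$prop_correct[keep]
  } else {
    abort("`x` must be classified trials, a tachometric_curve, or a sampled curve.")
  }
  if (length(xs) < 6) {
    abort("Need at least 6 occupied rPT bins to fit the 6-parameter model.")
  }
  res <- fit_sigmoid_core(xs, ys, al = 0.5, start_par = start, half_bin = hb)
  p <- res$par
  fit <- sigmoid_fit(b = p[1], ar = p[2], cl = p[3], dl = p[4],
                     cr = p[5], dr = p[6], al = 0.5)
  fit$mae <- res$value
  fit$converged <- isTRUE(res$converged)
  fit$n_bins <- length(xs)
  fit
}

#' Bootstrap confidence intervals for tachometric metrics
#'
#' Resamples trials with replacement, re-bins and re-fits the tachometric
#' curve for each replicate, and recomputes the three summary metrics: the
#' rPT at criterion accuracy, the probability of capture, and the asymptote
#' AR. Confidence intervals are percentile intervals of the replicate
#' distributions: 95% from the (2.5, 97.5) and 68% from the (16, 84)
#' percentiles. Replicate fits start from the full-sample solution; replicate
#' failures are dropped and counted.
#'
#' @inheritParams fit_tachometric
#' @param trials Classified trials with `rpt_ms` and `outcome`.
#' @param n_boot Number of bootstrap replicates (default 500).
#' @param seed Integer seed; results are deterministic given the seed.
#' @param level Criterion accuracy for [rpt_at_criterion()].
#' @param rpt_range Integration window for [capture_probability()].
#' @return An object of class `behavior_boot`: list with the full-sample
#'   `fit`, a `replicates` tibble, a `ci` tibble (one row per statistic), and
#'   diagnostics. `tidy()` returns the CI table.
#' @export
bootstrap_behavior <- function(trials, n_boot = 500, seed = 1,
                               bin_width_ms = 20, step_ms = 1, min_valid = 10,
                               level = 0.75, rpt_range = c(0, 300)) {
  stopifnot(is.data.frame(trials))
  fit <- fit_tachometric(trials, bin_width_ms = bin_width_ms,
                         step_ms = step_ms, min_valid = min_valid)
  valid <- trials$outcome %in% c("correct", "error")
  rpt <- trials$rpt_ms[valid]
  correct <- trials$outcome[valid] == "correct"
  n <- length(rpt)
  span <- c(floor(min(rpt)), ceiling(max(rpt)))
  centers <- seq(span[1], span[2], by = step_ms)
  start <- fit_par(fit)
  bounds <- fit_bounds(centers, 0.5)

  # resampling via per-trial multiplicities + windowed cumulative sums:
  # equivalent to re-binning a resampled trial table, without re-sorting
  ord <- order(rpt)
  cor_s <- correct[ord]
  hw <- bin_width_ms / 2
  lo_i <- findInterval(centers - hw, rpt[ord], left.open = TRUE)
  hi_i <- findInterval(centers + hw, rpt[ord], left.open = TRUE)
  rep_mat <- matrix(NA_real_, n_boot, 3)
  withr::with_seed(seed, {
    for (i in seq_len(n_boot)) {
      w <- tabulate(sample.int(n, n, replace = TRUE), n)[ord]
      cwc <- c(0, cumsum(w * cor_s))
      cwe <- c(0, cumsum(w * !cor_s))
      nc <- cwc[hi_i + 1] - cwc[lo_i + 1]
      ne <- cwe[hi_i + 1] - cwe[lo_i + 1]
      nv <- nc + ne
      keep <- nv >= min_valid
      if (sum(keep) < 6) next
      res <- fit_sigmoid_core(centers[keep], (nc / nv)[keep],
                              al = 0.5, start_par = start, maxit = 600,
                              half_bin = hw)
      p <- res$par
      f <- structure(list(b = p[1], al = 0.5, ar = p[2], cl = p[3],
                          dl = p[4], cr = p[5], dr = p[6]),
                     class = "sigmoid_fit")
      rep_mat[i, ] <- c(rpt_at_criterion(f, level),
                        p_capture_value(f, rpt_range),
                        p[2])
    }
  })
  failed <- is.na(rep_mat[, 3])
  n_failed <- sum(failed)
  replicates <- tibble::tibble(
    replicate = seq_len(n_boot)[!failed],
    rpt_at_criterion = rep_mat[!failed, 1],
    p_capture = rep_mat[!failed, 2],
    asymptote = rep_mat[!failed, 3]
  )
  pct <- function(v, q) as.numeric(stats::quantile(v, q, na.rm = TRUE, type = 7))
  stat_names <- c("rpt_at_criterion", "p_capture", "asymptote")
  est <- c(rpt_at_criterion(fit, level),
           capture_probability(fit, rpt_range)$p_capture, fit$ar)
  ci <- purrr::map2_dfr(stat_names, est, function(s, e) {
    v <- replicates[[s]]
    tibble::tibble(
      statistic = s, estimate = e,
      ci68_low = pct(v, 0.16), ci68_high = pct(v, 0.84),
      ci95_low = pct(v, 0.025), ci95_high = pct(v, 0.975)
    )
  })
  structure(
    list(fit = fit, replicates = replicates, ci = ci, n_boot = n_boot,
         n_failed = n_failed, seed = seed, level = level,
         rpt_range = rpt_range),
    class = "behavior_boot"
  )
}

#' @export
tidy.behavior_boot <- function(x, ...) x$ci

#' @export
glance.behavior_boot <- function(x, ...) {
  tibble::tibble(n_boot = x$n_boot, n_failed = x$n_failed, seed = x$seed)
}

#' @export
print.behavior_boot <- function(x, ...) {
  cat(sprintf("Trial-wise bootstrap (%d replicates, %d failed)\n",
              x$n_boot, x$n_failed))
  print(x$ci)
  invisible(x)
}

#' Normalized rPT distributions by outcome
#'
#' Running (unit-area) rPT histograms for correct and error trials, with the
#' distribution mode taken as the center of the maximal bin. The error-trial
#' fraction of all valid trials is attached as an attribute.
#'
#' @inheritParams tachometric_curve
#' @return A tibble (`outcome`, `bin_center_ms`, `density`) with attributes
#'   `modes` (tibble of per-outcome modes, `NA` for empty classes) and
#'   `error_fraction`.
#' @export
rpt_distributions <- function(trials, bin_width_ms = 20, step_ms = 1) {
  stopifnot(all(c("rpt_ms", "outcome") %in% names(trials)))
  valid <- trials$outcome %in% c("correct", "error")
  rpt <- trials$rpt_ms[valid]
  out <- trials$outcome[valid]
  span <- if (length(rpt) > 0) c(floor(min(rpt)), ceiling(max(rpt))) else c(0, 0)
  centers <- seq(span[1], span[2], by = step_ms)
  one <- function(cls) {
    x <- sort(rpt[out == cls])
    if (length(x) == 0) {
      return(list(df = tibble::tibble(outcome = character(),
                                      bin_center_ms = numeric(),
                                      density = numeric()),
                  mode = NA_real_))
    }
    cnt <- count_in_windows(x, centers - bin_width_ms / 2,
                            centers + bin_width_ms / 2)
    dens <- cnt / (length(x) * bin_width_ms)
    list(df = tibble::tibble(outcome = cls, bin_center_ms = centers,
                             density = dens),
         mode = centers[which.max(dens)])
  }
  rc <- one("correct"); re <- one("error")
  res <- dplyr::bind_rows(rc$df, re$df)
  attr(res, "modes") <- tibble::tibble(
    outcome = c("correct", "error"), mode_ms = c(rc$mode, re$mode)
  )
  attr(res, "error_fraction") <-
    if (length(out) > 0) mean(out == "error") else NA_real_
  res
}

#' Circular running histogram of saccade directions
#'
#' Density of saccade directions expressed relative to the target (target at
#' 0°, cue at ±180°), computed in running circular bins and normalized to
#' unit area over the circle.
#'
#' @inheritParams tachometric_curve
#' @param bin_deg Bin width in degrees (default 18).
#' @param step_deg Bin step in degrees (default 1).
#' @return A tibble of class `direction_histogram` with `dir_deg` (bin
#'   center, in (-180, 180]) and `density` (per degree; sums to 1/`step_deg`
#'   over the circle).
#' @export
direction_histogram <- function(trials, bin_deg = 18, step_deg = 1) {
  stopifnot(all(c("saccade_dir_deg", "target_dir_deg") %in% names(trials)))
  rel <- wrap_angle(trials$saccade_dir_deg - trials$target_dir_deg)
  rel <- rel[!is.na(rel)]
  centers <- seq(-180 + step_deg, 180, by = step_deg)
  n <- length(rel)
  if (n == 0) {
    dens <- rep(NA_real_, length(centers))
  } else {
    # unwrap by tiling one period on each side, then count half-open windows
    x <- sort(c(rel - 360, rel, rel + 360))
    cnt <- count_in_windows(x, centers - bin_deg / 2, centers + bin_deg / 2)
    dens <- cnt / (n * bin_deg)
  }
  structure(tibble::tibble(dir_deg = centers, density = dens),
            class = c("direction_histogram", class(tibble::tibble())),
            bin_deg = bin_deg, step_deg = step_deg, n = n)
}
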