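test_that("rPT follows the per-variant offset rule", {
  tr <- tibble::tibble(
    rt_ms = c(250, 180, 220, 320),
    gap_condition = c("overlap", "zero_gap", "gap100", "gap200")
  )
  expect_equal(compute_rpt(tr)$rpt_ms, c(350, 180, 120, 120))
  expect_error(compute_rpt(tibble::tibble(rt_ms = 100, gap_condition = "nope")),
               "Unknown gap condition")
})

test_that("saccades are classified against target and cue windows on the circle", {
  tr <- tibble::tibble(
    saccade_dir_deg = c(30, 170, 90, 315, 45),
    target_dir_deg = c(0, 0, 0, 0, 0),
    cue_dir_deg = c(180, 180, 180, 180, 180)
  )
  out <- classify_saccade(tr)$outcome
  # 315 wraps to -45: inclusive bound -> correct; 45 inclusive -> correct
  expect_equal(out, c("correct", "error", "intermediate", "correct", "correct"))
  expect_error(classify_saccade(tr, window_deg = 200), "window_deg")
  # missing saccade direction is unclassified
  tr$saccade_dir_deg[1] <- NA
  expect_equal(classify_saccade(tr)$outcome[1], "unclassified")
})

test_that("classification counts partition the trials for any window", {
  set.seed(3)
  tr <- tibble::tibble(
    saccade_dir_deg = runif(500, 0, 360),
    target_dir_deg = sample(c(0, 90, 180, 270), 500, TRUE)
  )
  tr$cue_dir_deg <- (tr$target_dir_deg + 180) %% 360
  for (w in c(20, 90, 180)) {
    out <- classify_saccade(tr, window_deg = w)$outcome
    expect_equal(sum(out %in% c("correct", "error", "intermediate")), 500)
  }
})

test_that("tachometric bins report the correct:valid ratio and Wilson CIs", {
  tr <- fixture_trials(rep(100, 10), rep(c("correct", "error"), c(8, 2)))
  cv <- tachometric_curve(tr, bin_width_ms = 20, step_ms = 20, min_valid = 1)
  row <- cv[cv$bin_center_ms == 100, ]
  expect_equal(row$prop_correct, 0.8)
  expect_equal(row$n_valid, 10)
  # all-correct bin pins the upper Wilson bound at 1
  tr2 <- fixture_trials(rep(100, 12), rep("correct", 12))
  row2 <- tachometric_curve(tr2, min_valid = 1)
  expect_true(all(row2$prop_correct[!row2$empty] == 1))
  expect_true(all(row2$ci_high[!row2$empty] == 1))
})

test_that("intermediate trials are excluded and no valid trials gives an empty curve", {
  tr <- fixture_trials(rep(100, 4), rep("correct", 4))
  tr$outcome <- c("correct", "error", "intermediate", "unclassified")
  cv <- tachometric_curve(tr, min_valid = 1)
  expect_equal(max(cv$n_valid), 2)
  none <- fixture_trials(rep(100, 3), rep("correct", 3))
  none$outcome <- "intermediate"
  expect_equal(nrow(tachometric_curve(none)), 0)
})

test_that("the curve is invariant to trial order and consistent across bin steps", {
  set.seed(5)
  tr <- fixture_trials(runif(2000, 0, 300),
                       sample(c("correct", "error"), 2000, TRUE, c(0.7, 0.3)))
  cv1 <- tachometric_curve(tr, min_valid = 1, rpt_range = c(10, 290))
  cv_shuf <- tachometric_curve(tr[sample.int(2000), ], min_valid = 1,
                               rpt_range = c(10, 290))
  expect_equal(as.data.frame(cv1), as.data.frame(cv_shuf))
  cv5 <- tachometric_curve(tr, step_ms = 5, min_valid = 1,
                           rpt_range = c(10, 290))
  shared <- dplyr::inner_join(as.data.frame(cv1), as.data.frame(cv5),
                              by = "bin_center_ms")
  expect_equal(shared$prop_correct.x, shared$prop_correct.y)
})

test_that("binomial CIs cover a flat true proportion at close to nominal rate", {
  set.seed(17)
  n <- 50000
  tr <- fixture_trials(runif(n, 0, 300),
                       ifelse(runif(n) < 0.75, "correct", "error"))
  cv <- tachometric_curve(tr, rpt_range = c(20, 280), min_valid = 1)
  covered <- mean(cv$ci_low <= 0.75 & cv$ci_high >= 0.75)
  expect_gte(covered, 0.9)
})

test_that("fitting noiseless curve samples recovers the parameters to 1%", {
  truth <- sigmoid_fit(b = 0.2, ar = 0.9, cl = 95, dl = 8, cr = 150, dr = 12)
  xs <- seq(20, 480, by = 1)
  pt <- tibble::tibble(bin_center_ms = xs, prop_correct = eval_sigmoid(truth, xs))
  f <- fit_tachometric(pt)
  for (p in c("b", "ar", "cl", "dl", "cr", "dr")) {
    expect_equal(f[[p]], truth[[p]], tolerance = 0.01)
  }
})

test_that("constant data pins the asymptote at the data level", {
  pt <- tibble::tibble(bin_center_ms = seq(0, 400, 2), prop_correct = 0.9)
  f <- fit_tachometric(pt)
  expect_equal(f$ar, 0.9, tolerance = 0.01)
})

test_that("fitted rise midpoints preserve the generative ordering", {
  mk <- function(cr, seed) {
    p <- behavior_sim_params(
      true_fit = sigmoid_fit(b = 0.2, ar = 0.9, cl = 95, dl = 8, cr = cr, dr = 12),
      n_trials = 12000, seed = seed)
    fit_tachometric(classify_saccade(generate_behavior(p)))
  }
  f_young <- mk(cr = 175, seed = 21)
  f_adult <- mk(cr = 135, seed = 22)
  expect_gt(f_young$cr, f_adult$cr)
})

test_that("too few occupied bins is an error", {
  tr <- fixture_trials(rep(100, 30), rep("correct", 30))
  expect_error(fit_tachometric(tr), "at least 6")
})

test_that("bootstrap is deterministic given the seed and stores its replicates", {
  p <- behavior_sim_params(n_trials = 6000, seed = 9)
  tr <- classify_saccade(generate_behavior(p))
  b1 <- bootstrap_behavior(tr, n_boot = 40, seed = 5)
  b2 <- bootstrap_behavior(tr, n_boot = 40, seed = 5)
  expect_equal(b1$ci, b2$ci)
  expect_equal(nrow(b1$replicates) + b1$n_failed, 40)
  expect_equal(tidy(b1)$statistic,
               c("rpt_at_criterion", "p_capture", "asymptote"))
  # percentile CIs nest: the 68% interval sits inside the 95% interval
  expect_true(all(b1$ci$ci95_low <= b1$ci$ci68_low + 1e-12))
  expect_true(all(b1$ci$ci68_high <= b1$ci$ci95_high + 1e-12))
})

test_that("rPT distributions are unit-area and locate a planted error mode", {
  set.seed(31)
  rpt <- c(runif(4000, 0, 300), rnorm(1000, 120, 10))
  out <- rep(c("correct", "error"), c(4000, 1000))
  d <- rpt_distributions(fixture_trials(rpt, out), bin_width_ms = 20)
  areas <- d |>
    dplyr::group_by(outcome) |>
    dplyr::summarise(a = sum(density) * 1)
  expect_equal(areas$a, rep(1, 2), tolerance = 0.02)
  modes <- attr(d, "modes")
  expect_equal(modes$mode_ms[modes$outcome == "error"], 120, tolerance = 5)
  expect_equal(attr(d, "error_fraction"), 0.2)
  # degenerate: no errors at all
  d2 <- rpt_distributions(fixture_trials(runif(100, 0, 300), rep("correct", 100)))
  expect_equal(nrow(d2[d2$outcome == "error", ]), 0)
  expect_true(is.na(attr(d2, "modes")$mode_ms[2]))
})

test_that("direction histogram handles delta, uniform, and mixture cases", {
  # all saccades on target: a single peak at 0
  tr <- tibble::tibble(saccade_dir_deg = 0, target_dir_deg = 0)[rep(1, 50), ]
  h <- direction_histogram(tr)
  # a point mass yields a plateau of maximal bins spanning the bin width
  expect_equal(h$density[h$dir_deg == 0], max(h$density))
  expect_true(all(h$density[abs(h$dir_deg) > 10] == 0))
  expect_equal(sum(h$density[abs(h$dir_deg) <= 9]), 1, tolerance = 1e-9)
  # evenly spaced directions: exactly flat at 1/360 per degree
  tru <- tibble::tibble(saccade_dir_deg = seq(0, 359.9, by = 0.1),
                        target_dir_deg = 0)
  hu <- direction_histogram(tru)
  expect_equal(hu$density, rep(1 / 360, nrow(hu)), tolerance = 1e-9)
})

test_that("capture mass near +/-180 matches the generative capture fraction", {
  flat8 <- sigmoid_fit(b = 0.5, ar = 0.8, cl = -200, dl = 1, cr = -200, dr = 1)
  p <- behavior_sim_params(true_fit = flat8, n_trials = 50000, seed = 13)
  tr <- generate_behavior(p)
  h <- direction_histogram(tr)
  cue_mass <- sum(h$density[abs(h$dir_deg) >= 135]) * 1
  expect_equal(cue_mass, 0.2, tolerance = 0.015)
})
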