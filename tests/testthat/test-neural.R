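test_that("single-spike density has the Gaussian peak and unit mass", {
  grid <- seq(-200, 200, by = 0.5)
  sd1 <- spike_density(0, grid, sigma_ms = 21)
  # peak in spikes/s: 1000 / (21 * sqrt(2*pi))
  expect_equal(max(sd1$rate_hz), 1000 / (21 * sqrt(2 * pi)), tolerance = 1e-9)
  mass <- sum(sd1$rate_hz) * 0.5 / 1000
  expect_equal(mass, 1, tolerance = 1e-4)
  # empty spike train: identically zero
  expect_true(all(spike_density(numeric(0), grid)$rate_hz == 0))
})

test_that("spike density mass scales with the number of spikes", {
  grid <- seq(-300, 600, by = 0.5)
  spikes <- c(-50, 0, 10, 200, 330)
  m <- sum(spike_density(spikes, grid)$rate_hz) * 0.5 / 1000
  expect_equal(m, length(spikes), tolerance = 5 * 1e-4)
})

test_that("population average reduces correctly for degenerate neuron sets", {
  grid <- seq(-100, 100, by = 2)
  spikes <- list(c(-40, 0, 35), c(-10, 20))
  rec_a <- tibble::tibble(neuron_id = "a", cue_on_ms = 0,
                          spike_times_ms = spikes)
  # duplicated neuron: across-neuron SEM is exactly zero
  rec <- dplyr::bind_rows(rec_a, dplyr::mutate(rec_a, neuron_id = "b"))
  pa <- population_average(rec, align = "cue_on_ms", t_grid_ms = grid)
  expect_equal(pa$n_neurons[1], 2)
  expect_true(all(pa$sem_hz == 0))
  # doubling every spike doubles the trace: mean = 1.5x, SEM = 0.5x original
  rec_b <- dplyr::mutate(rec_a, neuron_id = "b",
                         spike_times_ms = purrr::map(spikes, rep, each = 2))
  pa2 <- population_average(dplyr::bind_rows(rec_a, rec_b),
                            align = "cue_on_ms", t_grid_ms = grid)
  base <- population_average(rec_a, align = "cue_on_ms", t_grid_ms = grid)
  expect_true(is.na(base$sem_hz[1]))  # single neuron: SEM undefined
  expect_equal(pa2$mean_hz, 1.5 * base$mean_hz)
  expect_equal(pa2$sem_hz, 0.5 * base$mean_hz)
})

test_that("population average tracks the generative rate of simulated neurons", {
  np <- neuron_sim_params(baseline_hz = 15, cue_amp_hz = 25, delay_hz = 0,
                          presac_amp_hz = 0, out_of_rf_gain = 1,
                          n_trials_odr = 150)
  rec <- dplyr::bind_rows(purrr::map(1:6, function(i) {
    generate_odr_neuron(np, neuron_id = paste0("n", i), seed = 100 + i)
  }))
  grid <- seq(0, 400, by = 10)
  pa <- population_average(rec, align = "cue_on_ms", t_grid_ms = grid)
  truth <- np$baseline_hz + tachometric:::cue_transient_hz(grid, np)
  # away from kernel edge effects the trace follows the generative rate
  mid <- grid >= 100 & grid <= 350
  expect_true(all(abs(pa$mean_hz[mid] - truth[mid]) <= 4 * pa$sem_hz[mid] + 1))
})

test_that("window rates count half-open windows", {
  expect_equal(window_rate(c(10, 20, 99.9), c(0, 100)), 30)
  expect_equal(window_rate(numeric(0), c(0, 100)), 0)
  # spike exactly at the window end is excluded
  expect_equal(window_rate(c(100), c(0, 100)), 0)
  expect_equal(window_rate(c(0), c(0, 100)), 10)
  expect_error(window_rate(c(1), c(100, 100)))
})

test_that("a constructed cue response is detected with the right RF", {
  np <- neuron_sim_params(baseline_hz = 10, cue_amp_hz = 30, delay_hz = 5,
                          presac_amp_hz = 15, rf_dir_deg = 90,
                          n_trials_odr = 160, n_trials_anti = 110)
  trials <- classify_saccade(generate_behavior(
    behavior_sim_params(n_trials = 110, seed = 31)))
  rec <- dplyr::bind_rows(
    generate_odr_neuron(np, seed = 31),
    generate_antisaccade_neuron(np, trials, seed = 32))
  cls <- classify_neuron(rec)
  expect_true(cls$visual)
  expect_equal(cls$rf_dir_deg, 90)
  expect_true(cls$presaccadic)
  expect_true(cls$is_vm)
})

test_that("classification requires both tasks", {
  np <- neuron_sim_params(n_trials_odr = 20)
  odr <- generate_odr_neuron(np, seed = 1)
  expect_error(classify_neuron(odr), "both ODR and antisaccade")
})

test_that("cue-saccade differential matches the generative rate difference", {
  np <- neuron_sim_params(baseline_hz = 10, cue_amp_hz = 20, delay_hz = 6,
                          presac_amp_hz = 12, n_trials_odr = 160)
  rec <- dplyr::bind_rows(purrr::map(1:25, function(i) {
    generate_odr_neuron(np, neuron_id = paste0("n", i), seed = 200 + i)
  }))
  res <- cue_saccade_differential(rec)
  # generative oracle: transient mean over 50-150 ms post-cue minus the ramp
  # mean over -100..0 ms (delay and baseline are present in both windows)
  tr_mean <- mean(tachometric:::cue_transient_hz(seq(50.25, 150, 0.5), np))
  ramp_mean <- mean(tachometric:::presac_ramp_hz(seq(-99.75, 0, 0.5), np))
  expected <- tr_mean - ramp_mean
  sem <- res$summary$sem_delta_hz[1]
  expect_lt(abs(res$summary$mean_delta_hz[1] - expected), 3 * sem)
  expect_equal(nrow(res$neurons), 25)
})

test_that("group contrast on identical group data is non-significant", {
  np <- neuron_sim_params(n_trials_odr = 40)
  rec <- dplyr::bind_rows(purrr::map(1:8, function(i) {
    r <- generate_odr_neuron(np, neuron_id = paste0("n", i), seed = 300 + i)
    r$group <- if (i <= 4) "young" else "adult"
    r
  }))
  res <- cue_saccade_differential(rec, group = "group", n_perm = 2000, seed = 4)
  expect_true(res$contrast$p_value > 0.001)
  expect_equal(nrow(res$summary), 2)
})

test_that("ROC area reproduces limit cases and tie handling", {
  expect_equal(roc_area(c(3, 5, 7, 9), c(3, 5, 7, 9)), 0.5)
  expect_equal(roc_area(c(5, 6, 7), c(1, 2, 3)), 1)
  expect_equal(roc_area(c(1, 2, 3), c(5, 6, 7)), 0)
  # exhaustive enumeration: 2 of 4 pairs favorable
  expect_equal(roc_area(c(1, 3), c(2, 2)), 0.5)
  expect_true(is.na(roc_area(numeric(0), c(1, 2))))
})

test_that("ROC area is tie-symmetric and matches the pairwise oracle", {
  set.seed(23)
  for (i in 1:60) {
    a <- rpois(sample(2:50, 1), sample(1:8, 1))
    b <- rpois(sample(2:50, 1), sample(1:8, 1))
    expect_equal(roc_area(a, b) + roc_area(b, a), 1)
    expect_equal(roc_area(a, b), roc_oracle(a, b), tolerance = 1e-12)
  }
})

test_that("pooling centers each neuron at the midpoint of its condition means", {
  rec <- fixture_counts_recording("n1", n_cue = 2, cue_count = 10,
                                  n_sac = 2, sac_count = 4)
  cc <- pool_and_center(rec)
  th <- attr(cc, "thetas")
  expect_equal(th$mu_cue, 10)
  expect_equal(th$mu_sac, 4)
  expect_equal(th$theta, 7)
  expect_equal(sort(unique(cc$centered)), c(-3, 3))
  # neurons with equal condition means center to zero
  rec0 <- fixture_counts_recording("n2", 3, 5, 3, 5)
  cc0 <- pool_and_center(rec0)
  expect_true(all(cc0$centered == 0))
})

test_that("neurons with a single condition are excluded with diagnostics", {
  rec <- dplyr::bind_rows(
    fixture_counts_recording("full", 2, 6, 2, 2),
    fixture_counts_recording("cue_only", 3, 5, 0, 0))
  cc <- pool_and_center(rec)
  expect_equal(attr(cc, "excluded"), "cue_only")
  expect_false("cue_only" %in% cc$neuron_id)
})

test_that("balanced pooled centered means are equal and opposite", {
  set.seed(41)
  recs <- purrr::map(1:5, function(i) {
    k <- sample(2:6, 1)
    fixture_counts_recording(paste0("n", i), k, sample(2:12, 1),
                             k, sample(2:12, 1))
  })
  cc <- pool_and_center(dplyr::bind_rows(recs))
  m_cue <- mean(cc$centered[cc$condition == "cue_in"])
  m_sac <- mean(cc$centered[cc$condition == "sac_in"])
  expect_equal(m_cue, -m_sac, tolerance = 1e-12)
})

test_that("neurometric curve is flat at 0.5 under the null and bounded in [0,1]", {
  set.seed(51)
  n <- 4000
  cc <- fixture_centered(runif(n, 60, 310),
                         sample(c("cue_in", "sac_in"), n, TRUE),
                         rnorm(n))
  nc <- neurometric_curve(cc, min_n = 50)
  ok <- !is.na(nc$s_roc)
  expect_true(all(nc$s_roc[ok] >= 0 & nc$s_roc[ok] <= 1))
  expect_lt(max(abs(nc$s_roc[ok] - 0.5)), 0.09)
  expect_lt(mean(abs(nc$s_roc[ok] - 0.5)), 0.03)
})

test_that("bins below the occupancy threshold are flagged", {
  cc <- fixture_centered(rep(150, 10), rep(c("cue_in", "sac_in"), 5), rnorm(10))
  nc <- neurometric_curve(cc, min_n = 20)
  expect_true(all(is.na(nc$s_roc)))
  nc2 <- neurometric_curve(cc, min_n = 10)
  expect_false(all(is.na(nc2$s_roc)))
})

test_that("neurometric curve ignores neuron order and per-neuron count offsets", {
  trials <- classify_saccade(generate_behavior(
    behavior_sim_params(n_trials = 300, seed = 61)))
  np <- neuron_sim_params(n_trials_anti = 300)
  rec <- dplyr::bind_rows(
    generate_antisaccade_neuron(np, trials, neuron_id = "a", seed = 62),
    generate_antisaccade_neuron(np, trials, neuron_id = "b", seed = 63))
  base <- neurometric_curve(pool_and_center(rec), min_n = 10)
  shuf <- neurometric_curve(pool_and_center(rec[sample.int(nrow(rec)), ]),
                            min_n = 10)
  expect_equal(base$s_roc, shuf$s_roc)
  # add a constant 6 spikes inside the presaccadic window of every trial of
  # neuron "a": theta absorbs the offset, the curve is unchanged
  rec2 <- rec
  extra <- seq(-48, -2, length.out = 6)
  idx <- which(rec2$neuron_id == "a")
  rec2$spike_times_ms[idx] <- purrr::map(idx, function(i) {
    sort(c(rec2$spike_times_ms[[i]], rec2$saccade_on_ms[i] + extra))
  })
  shifted <- neurometric_curve(pool_and_center(rec2), min_n = 10)
  expect_equal(base$s_roc, shifted$s_roc)
})

test_that("short/long pooled signals respect their range conventions", {
  # a boundary trial at exactly 170 ms belongs to the long range only
  cc <- fixture_centered(c(rep(170, 30), rep(100, 4)),
                         rep(c("cue_in", "sac_in"), 17),
                         c(rep(c(2, -2), 15), 1, -1, 1, -1))
  res <- sroc_binned(cc, n_boot = 50, seed = 1)
  expect_equal(res$by_range$n_cue[res$by_range$range == "long"], 15)
  expect_equal(res$by_range$n_cue[res$by_range$range == "short"], 2)
})

test_that("cue dominance restricted to short rPTs orders the binned signals", {
  set.seed(71)
  n <- 1200
  rpt <- runif(n, 70, 300)
  cond <- rep(c("cue_in", "sac_in"), n / 2)
  shift <- ifelse(cond == "cue_in" & rpt < 170, 1.5, 0)
  cc <- fixture_centered(rpt, cond, rnorm(n) + shift)
  res <- sroc_binned(cc, n_boot = 200, seed = 2)
  s <- res$by_range
  expect_gt(s$s_roc[s$range == "short"], s$s_roc[s$range == "long"])
  expect_lt(res$difference$p_value, 0.05)
})

test_that("s_roc bootstrap is seed-deterministic and keeps its replicates", {
  a <- rpois(40, 6); b <- rpois(35, 4)
  b1 <- bootstrap_sroc(a, b, n_boot = 300, seed = 9)
  b2 <- bootstrap_sroc(a, b, n_boot = 300, seed = 9)
  expect_identical(b1, b2)
  expect_length(b1$replicates, 300)
  expect_true(b1$ci95[1] <= b1$ci68[1] && b1$ci68[2] <= b1$ci95[2])
})

test_that("permutation tests enumerate exactly and bound p in (0, 1]", {
  res <- permutation_test(c(1, 2), c(3, 4))
  expect_true(res$exact)
  expect_equal(res$p_value, 1 / 3)
  # identical samples: the observed statistic is the null's center
  same <- permutation_test(c(2, 5, 9), c(2, 5, 9))
  expect_equal(same$p_value, 1)
  # Monte-Carlo branch with the add-one correction never returns 0
  set.seed(3)
  big <- permutation_test(rnorm(40, 3), rnorm(40), n_perm = 500, seed = 5)
  expect_false(big$exact)
  expect_true(big$p_value > 0 && big$p_value <= 1)
  expect_error(permutation_test(1:3, 1:4, paired = TRUE), "equal length")
})

test_that("paired sign-flip enumeration matches a hand-computed case", {
  # d = (2, 2): 4 sign patterns, |mean| >= 2 for (+,+) and (-,-): p = 1/2
  res <- permutation_test(c(3, 5), c(1, 3), paired = TRUE)
  expect_true(res$exact)
  expect_equal(res$p_value, 0.5)
})
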