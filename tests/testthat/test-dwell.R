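test_that("first and last segments are censored when harvesting dwells", {
  p <- make_path(rep(c(1L, 2L, 1L), c(10, 30, 20)))
  ds <- extract_dwells(list(p), 2, n_states = 2)
  expect_equal(ds$dwells, 3.0)
  ds1 <- extract_dwells(list(p), 1, n_states = 2)
  expect_length(ds1$dwells, 0)
  expect_equal(ds1$censored_first, 1)
  expect_equal(ds1$censored_last, 1)
  single <- make_path(rep(2L, 40))
  ds2 <- extract_dwells(list(single), 2, n_states = 2)
  expect_length(ds2$dwells, 0)
  expect_equal(ds2$censored_first, 1)
  expect_error(extract_dwells(list(p), 5, n_states = 2), "unknown state")
})

test_that("dwell rates follow the inverse-mean estimator", {
  ds <- structure(list(dwells = rep(2, 100), frame_interval = 0.1),
                  class = "dwell_set")
  r <- rate_from_dwells(ds)
  expect_equal(r$rate, 0.5)
  expect_equal(r$se, 0.05)
  expect_error(rate_from_dwells(structure(list(dwells = c(1, 2)),
                                          class = "dwell_set")), "usable")
})

test_that("exponential dwell samples recover the generative rate", {
  set.seed(41)
  ds <- structure(list(dwells = rexp(1e4, 0.0653), frame_interval = 0.1),
                  class = "dwell_set")
  r <- rate_from_dwells(ds)
  expect_lt(abs(r$rate - 0.0653), 2 * r$se)
  expect_false(r$nonexponential)
})

test_that("a two-population dwell mixture is flagged as non-exponential", {
  set.seed(42)
  d <- c(rexp(500, 1), rexp(500, 0.05))
  ds <- structure(list(dwells = d, frame_interval = 0.1),
                  class = "dwell_set")
  expect_true(rate_from_dwells(ds)$nonexponential)
})

test_that("evolution maps synchronize at the first threshold crossing", {
  step <- make_fret(c(rep(0.3, 37), rep(0.8, 30)))
  flat <- make_fret(rep(0.3, 67), id = "t2")
  em <- evolution_map(list(step, flat), threshold = 0.5,
                      window = c(-2, 2), bins = 12)
  expect_equal(em$n_traces, 1)
  expect_equal(em$n_excluded, 1)
  # time zero is the first frame at 0.8; pre-zero columns sit in the 0.3 bin
  pre <- em$time_offsets < 0
  b03 <- findInterval(0.3, em$bin_edges)
  expect_true(all(em$counts[b03, pre] == em$n_contrib[pre]))
  b08 <- findInterval(0.8, em$bin_edges)
  post <- em$time_offsets >= 0
  expect_true(all(em$counts[b08, post] == em$n_contrib[post]))
})

test_that("evolution map columns conserve contributing traces", {
  fr <- sim_corrected("IC7", 15, 51, duration = 60)
  em <- evolution_map(fr, window = c(-5, 10))
  expect_equal(colSums(em$counts), em$n_contrib)
  expect_true(all(colSums(em$density[, em$n_contrib > 0]) - 1 < 1e-12))
})

test_that("high-FRET band persists after synchronization in stalled IC7", {
  fr <- sim_corrected("IC7", 40, 52, duration = 60)
  em <- evolution_map(fr, window = c(-5, 10), bins = 12)
  hi_bins <- hist_mid <- (head(em$bin_edges, -1) + tail(em$bin_edges, -1)) / 2
  hi <- which(hi_bins > 0.6)
  post10 <- which.min(abs(em$time_offsets - 10))
  expect_gt(sum(em$density[hi, post10]), 0.5)
})

test_that("washout timecourses refit only the weights of a frozen template", {
  set.seed(43)
  template <- fit_mixture(build_histogram(
    c(rnorm(6000, 0.376, 0.06), rnorm(6000, 0.811, 0.06))), 2, seed = 1)
  gen_hist <- function(w_hi, n = 4000) {
    n_hi <- rbinom(1, n, w_hi)
    build_histogram(c(rnorm(n - n_hi, 0.376, 0.06), rnorm(n_hi, 0.811, 0.06)))
  }
  flat <- washout_timecourse(lapply(rep(0.6, 5), gen_hist), template)
  expect_true(all(abs(flat$table$fraction_2 - 0.6) < 0.05))
  decays <- washout_timecourse(lapply(c(0.8, 0.6, 0.45, 0.33, 0.25, 0.18),
                                      gen_hist), template)
  expect_true(all(diff(decays$table$fraction_2) < 0.05))
  expect_true(all(decays$table$flagged == 0))
})

test_that("single-exponential fits recover rates and are honest about flats", {
  s <- simulate_2ap_decay(k = 0.0165, f0 = 1, f_inf = 0.55, duration = 400)
  f <- fit_decay(s)
  expect_equal(f$rate, 0.0165, tolerance = 1e-6)
  expect_false(f$flagged)
  expect_equal(f$half_life * f$rate, log(2), tolerance = 1e-9)
  flat <- fit_decay(data.frame(time = 1:20, value = rep(1, 20)))
  expect_true(flat$flagged)
  expect_lt(abs(flat$rate), 0.01)
})

test_that("noisy half-life recovery stays within ten percent in the median", {
  k <- log(2) / 4.1
  hl <- vapply(1:50, function(i) {
    s <- simulate_2ap_decay(k = k, f0 = 0.85, f_inf = 0, duration = 11,
                            noise_sd = 0.03 * 0.85, seed = 500 + i, dt = 1)
    fit_decay(s)$half_life
  }, numeric(1))
  expect_lt(abs(median(hl) - 4.1) / 4.1, 0.10)
})

test_that("branching classification follows its definitions", {
  hi <- 0.7; lo <- 0.3
  tr_transient <- make_fret(c(rep(hi, 30), rep(lo, 20), rep(hi, 30)))
  tr_irrev <- make_fret(c(rep(hi, 30), rep(lo, 50)), id = "t2")
  tr_none <- make_fret(rep(hi, 80), id = "t3")
  out <- classify_post_washout(list(tr_transient, tr_irrev, tr_none),
                               high_threshold = 0.5)
  expect_equal(unname(out$counts), c(1L, 1L, 1L))
  # sub-resolution flicker is ignored
  tr_flicker <- make_fret(c(rep(hi, 30), rep(lo, 2), rep(hi, 30)))
  out2 <- classify_post_washout(list(tr_flicker), high_threshold = 0.5)
  expect_equal(unname(out2$fractions["no_drop"]), 1)
  # traces not starting high are rejected
  out3 <- classify_post_washout(list(make_fret(rep(lo, 30)), tr_none),
                                high_threshold = 0.5)
  expect_equal(out3$n_rejected, 1)
})

test_that("dwell correction is small when all events are well resolved", {
  # clean alternation with 10 s dwells: correction stays within a few percent
  states <- rep(rep(c(1L, 2L), 25), each = 100)
  p <- make_path(states)
  r <- dwell_rate_corrected(list(p), 2, n_states = 2, resolution_frames = 3)
  expect_equal(r$rate_raw, 1 / 10, tolerance = 1e-9)
  expect_equal(r$rate, r$rate_raw, tolerance = 0.1)
  expect_lt(r$q, 0.1)
})
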