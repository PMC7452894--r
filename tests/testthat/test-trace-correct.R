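test_that("direct-excitation subtraction uses the post-donor-bleach mean", {
  donor <- c(rep(500, 50), rep(0, 50))
  acceptor <- c(rep(300, 50), rep(50, 50))
  tr <- make_trace(donor, acceptor, donor_bleach_frame = 51L)
  out <- subtract_direct_excitation(tr)
  expect_equal(out$direct_offset, 50)
  expect_equal(out$acceptor, acceptor - 50)
  expect_false(out$direct_fallback)
})

test_that("simulated direct excitation is recovered per trace", {
  traces <- simulate_traces("dna_only", n_traces = 80, seed = 9)
  traces <- subtract_direct_excitation(traces)
  per_trace <- vapply(traces, function(tr) tr$direct_offset, numeric(1))
  own <- per_trace[!vapply(traces, function(tr) tr$direct_fallback, logical(1))]
  expect_gt(length(own), 5)
  expect_equal(median(own), 80, tolerance = 6 / 80)
})

test_that("traces without donor bleach fall back to the movie median", {
  good <- make_trace(c(rep(500, 60), rep(0, 40)),
                     c(rep(300, 60), rep(72, 40)), donor_bleach_frame = 61L)
  bad <- make_trace(rep(480, 100), rep(310, 100))
  out <- subtract_direct_excitation(list(good, bad))
  expect_false(out[[1]]$direct_fallback)
  expect_true(out[[2]]$direct_fallback)
  expect_equal(out[[2]]$direct_offset, 72)
  expect_equal(out[[2]]$acceptor, rep(310 - 72, 100))
})

test_that("the apparent-E formula follows its printed definition", {
  tr <- make_trace(c(460, 100, 0), c(540, 8, 250))
  f <- compute_fret(tr, correction_params(beta = 0.08))
  expect_equal(f$e_fret[1], (540 - 0.08 * 460) / 1000)   # 0.5032
  expect_equal(f$e_fret[2], 0)                           # I_A = beta I_D
  expect_equal(f$e_fret[3], 1)                           # donor dark
})

test_that("zero-total and post-bleach frames are masked, not propagated", {
  tr <- make_trace(c(500, 0, 500, 500), c(300, 0, 300, 300),
                   acceptor_bleach_frame = 4L)
  f <- compute_fret(tr, correction_params(beta = 0.08))
  expect_equal(f$masked, c(FALSE, TRUE, FALSE, TRUE))
  expect_true(all(is.finite(fret_values(f))))
})

test_that("gamma-corrected E matches the printed formula and its gamma=1 identity", {
  tr <- make_trace(c(500, 0), c(500, 400))
  pg <- correction_params(beta = 0.08, gamma = 1.51)
  f <- compute_fret_gamma(tr, pg)
  expect_equal(f$e_fret[1], 460 / (1.51 * 540 + 460), tolerance = 1e-12)
  expect_equal(f$e_fret[2], 1)                           # donor dark, any gamma
  set.seed(1)
  D <- runif(50, 10, 1000); A <- runif(50, 10, 1000)
  tr2 <- make_trace(D, A)
  f_g1 <- compute_fret_gamma(tr2, correction_params(beta = 0.08, gamma = 1))
  f_ap <- compute_fret(tr2, correction_params(beta = 0.08))
  expect_equal(f_g1$e_fret, f_ap$e_fret, tolerance = 1e-12)
  expect_error(compute_fret_gamma(tr2, correction_params(beta = 0.08)),
               "gamma")
})

test_that("apparent E is invariant to rescaling both channels", {
  set.seed(2)
  D <- runif(30, 50, 800); A <- runif(30, 50, 800)
  f1 <- compute_fret(make_trace(D, A), correction_params(beta = 0.08))
  f2 <- compute_fret(make_trace(3.7 * D, 3.7 * A),
                     correction_params(beta = 0.08))
  expect_equal(f1$e_fret, f2$e_fret, tolerance = 1e-12)
})

test_that("a constructed acceptor-bleach step of 302/200 gives gamma 1.51", {
  donor <- c(rep(200, 40), rep(400, 40))
  acceptor <- c(rep(502, 40), rep(200, 40))
  tr <- make_trace(donor, acceptor, acceptor_bleach_frame = 41L)
  flat <- make_trace(rep(400, 80), rep(32, 80), acceptor_bleach_frame = 41L)
  g <- estimate_gamma(list(tr, flat))
  expect_equal(g$n_events, 1)              # degenerate no-FRET event excluded
  expect_equal(g$gamma, 1.51, tolerance = 1e-12)
})

test_that("estimate_gamma fails informatively without usable events", {
  tr <- make_trace(rep(500, 20), rep(300, 20))
  expect_error(estimate_gamma(list(tr)), "manually")
})

test_that("donor-only molecules give beta exactly and via simulation", {
  tr <- make_trace(rep(500, 50), rep(40, 50), acceptor_present = FALSE)
  expect_equal(estimate_beta(list(tr))$beta, 0.08, tolerance = 1e-9)
  expect_error(estimate_beta(list(make_trace(rep(1, 5), rep(1, 5)))),
               "donor-only")
  ph0 <- photophysics(beta = 0, donor_bleach_rate = 0.002,
                      acceptor_bleach_rate = 0)
  traces <- simulate_traces("dna_only", phys = ph0, n_traces = 40, seed = 5,
                            acceptor_fraction = 0)
  expect_lt(estimate_beta(traces)$beta, 0.005)
})

test_that("uncorrected donor-only FRET peaks at beta/(1+beta)", {
  traces <- simulate_traces("dna_only", n_traces = 60, seed = 6,
                            acceptor_fraction = 0)
  f <- lapply(traces, compute_fret, params = correction_params(beta = 0))
  vals <- unlist(lapply(f, block_average))
  expect_equal(mean(vals), 0.08 / 1.08, tolerance = 0.01 / 0.074)
})

test_that("trace filtering keeps single-pair acceptor-bearing molecules", {
  mk <- function(acc, single) make_trace(rep(1, 5), rep(1, 5),
                                         acceptor_present = acc,
                                         single_pair = single)
  traces <- c(replicate(6, mk(TRUE, TRUE), simplify = FALSE),
              replicate(4, mk(FALSE, TRUE), simplify = FALSE))
  out <- filter_traces(traces)
  expect_equal(out$report$n_retained, 6)
  expect_equal(out$report$n_no_acceptor, 4)
  all_good <- replicate(5, mk(TRUE, TRUE), simplify = FALSE)
  expect_equal(length(filter_traces(all_good)$traces), 5)
  empty <- filter_traces(list())
  expect_true(empty$report$empty_input)
  expect_equal(length(empty$traces), 0)
})

test_that("simulated single-pair fraction is recovered by the filter report", {
  traces <- simulate_traces("dna_only", n_traces = 300, seed = 8,
                            single_pair_fraction = 0.7)
  frac <- filter_traces(traces)$report$fraction_retained
  expect_equal(frac, 0.7, tolerance = 3 * sqrt(0.7 * 0.3 / 300) / 0.7)
})

test_that("block averaging uses non-overlapping complete blocks", {
  expect_equal(block_average(make_fret(rep(0.5, 23)), 5), rep(0.5, 4))
  expect_length(block_average(make_fret(rnorm(12)), 5), 2)
  expect_equal(block_average(make_fret(rep(c(0.2, 0.8), 6)), 2), rep(0.5, 6))
  expect_length(block_average(make_fret(rep(0.5, 3)), 5), 0)
})
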