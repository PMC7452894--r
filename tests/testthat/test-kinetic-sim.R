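test_that("identical seeds give bit-identical trajectories and traces", {
  fx <- fixtures("IC2")
  t1 <- simulate_ctmc(fx$scheme, fx$protocol, seed = 42)
  t2 <- simulate_ctmc(fx$scheme, fx$protocol, seed = 42)
  expect_identical(t1, t2)
  r1 <- render_trace(t1, fx$phys, seed = 7)
  r2 <- render_trace(t2, fx$phys, seed = 7)
  expect_identical(r1$donor, r2$donor)
  expect_identical(r1$acceptor, r2$acceptor)
})

test_that("symmetric two-state chain spends half its time in each state", {
  sc <- two_state_scheme(k12 = 1, k21 = 1)
  traj <- simulate_ctmc(sc, protocol(1e4), seed = 1)
  occ_A <- occupancy_time(traj, 1) / traj$t_end
  expect_equal(occ_A, 0.5, tolerance = 0.02 / 0.5)
})

test_that("empirical occupancies match the matrix-exponential oracle", {
  sc <- kinetic_scheme(
    states = data.frame(label = c("closed", "open", "scrunched"),
                        fret_mean = c(0.135, 0.376, 0.563),
                        fret_sd = rep(0.08, 3)),
    rates = data.frame(from = c("closed", "open", "open", "scrunched"),
                       to = c("open", "closed", "scrunched", "open"),
                       rate = c(0.8, 0.5, 1.0, 0.6)),
    initial = c(1, 0, 0))
  t_eval <- 2
  n_rep <- 4000
  seed_at_t <- function(i) {
    traj <- simulate_ctmc(sc, protocol(t_eval))
    traj$state_sequence[findInterval(t_eval - 1e-9, traj$jump_times)]
  }
  set.seed(123)
  states <- vapply(seq_len(n_rep), seed_at_t, integer(1))
  emp <- tabulate(states, 3) / n_rep
  Q <- scheme_generator(sc)
  p_t <- as.numeric(c(1, 0, 0) %*% pracma::expm(Q * t_eval))
  se <- sqrt(p_t * (1 - p_t) / n_rep)
  expect_true(all(abs(emp - p_t) <= 3 * se))
})

test_that("washout events zero NTP-dependent transitions permanently", {
  fx <- fixtures("IC2")
  prot <- protocol(120, events = list(list(time = 60, ntp = c(NTP = 0))))
  scr <- match("scrunched", fx$scheme$states$label)
  for (seed in 1:100) {
    traj <- simulate_ctmc(fx$scheme, prot, seed = seed)
    into_scr <- which(traj$state_sequence == scr)
    into_scr <- into_scr[into_scr > 1]      # actual jumps, not initial state
    expect_true(all(traj$jump_times[into_scr] <= 60))
  }
})

test_that("noiseless rendering is exactly inverted by the apparent-E formula", {
  fx <- fixtures("dna_only")
  traj <- simulate_ctmc(fx$scheme, fx$protocol, seed = 1)
  tr <- render_trace(traj, fx$phys, noiseless = TRUE)
  tr$acceptor <- tr$acceptor - fx$phys$direct_excitation
  f <- compute_fret(tr, correction_params(beta = fx$phys$beta))
  expect_equal(fret_values(f), rep(0.138, length(fret_values(f))),
               tolerance = 1e-12)
})

test_that("no transfer, no leakage, no direct excitation leaves acceptor empty", {
  ph <- photophysics(beta = 0, gamma = 1, direct_excitation = 0,
                     background_sd = 0, donor_bleach_rate = 0,
                     acceptor_bleach_rate = 0)
  sc <- kinetic_scheme(states = data.frame(label = "bare", fret_mean = 0,
                                           fret_sd = 0))
  traj <- simulate_ctmc(sc, protocol(10), seed = 1)
  tr <- render_trace(traj, ph, noiseless = TRUE)
  expect_true(all(tr$acceptor == 0))
  expect_true(all(tr$donor == ph$total_rate))
})

test_that("acceptor-photobleach step ratio recovers gamma", {
  traces <- simulate_traces("gamma_cal", n_traces = 60, seed = 4)
  traces <- subtract_direct_excitation(traces)
  g <- estimate_gamma(traces)
  expect_gt(g$n_events, 20)
  expect_equal(g$gamma, 1.51, tolerance = 0.05 / 1.51)
})

test_that("photophysics constructor rejects negative parameters", {
  expect_error(photophysics(total_rate = -5), "non-negative")
  expect_error(photophysics(beta = 1.2), "beta")
})

test_that("2AP decay generator honours its closed form", {
  flat <- simulate_2ap_decay(k = 0, f0 = 2, f_inf = 0.5, duration = 50)
  expect_true(all(flat$value == 2))
  s <- simulate_2ap_decay(k = 0.0165, f0 = 1, f_inf = 0.4, duration = 100)
  expect_equal(s$value[1], 1)              # t = 0 boundary
  expect_equal(s$value[s$time == 42], 0.4 + 0.6 * exp(-0.0165 * 42),
               tolerance = 1e-12)
  rising <- simulate_2ap_decay(k = 0.1, f0 = 0.2, f_inf = 1, duration = 10)
  expect_true(all(diff(rising$value) > 0))
})

test_that("packaged fixtures carry the reported state levels and rates", {
  expect_equal(scheme_fret_mean(fixtures("IC7")$scheme, "scrunched"), 0.811)
  expect_equal(scheme_rate(fixtures("IC2")$scheme, "scrunched", "open"), 0.305)
  expect_equal(scheme_rate(fixtures("IC7")$scheme, "scrunched", "open"), 0.0653)
  expect_equal(scheme_fret_mean(fixtures("templ_11")$scheme, "elongation"),
               0.442)
  expect_equal(scheme_fret_mean(fixtures("dna_only")$scheme, "bare"), 0.138)
  expect_error(fixtures("IC99"), "available")
  expect_equal(fixture_ensemble("walk_9")$k, 0.0165)
})

test_that("frame occupancy integrates the path exactly", {
  sc <- two_state_scheme()
  traj <- structure(list(jump_times = c(0, 0.25), state_sequence = c(1L, 2L),
                         t_end = 0.5, states = sc$states),
                    class = "state_trajectory")
  occ <- frame_occupancy(traj, frame_interval = 0.1)
  expect_equal(nrow(occ), 5)
  expect_equal(occ[1, ], c(1, 0))
  expect_equal(occ[3, ], c(0.5, 0.5))      # jump mid-frame
  expect_equal(occ[5, ], c(0, 1))
  expect_true(all(abs(rowSums(occ) - 1) < 1e-12))
})
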