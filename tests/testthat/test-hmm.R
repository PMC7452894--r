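brute_force_viterbi <- function(y, means, sds, A, pi) {
  K <- length(means); T <- length(y)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T)))
  lp <- apply(paths, 1, function(s) {
    v <- log(pi[s[1]]) + sum(dnorm(y, means[s], sds[s], log = TRUE))
    if (T > 1) v <- v + sum(log(A[cbind(s[-T], s[-1])]))
    v
  })
  list(best = max(lp), path = paths[which.max(lp), ])
}

test_that("single-state fit reduces to the sample mean exactly", {
  fr <- lapply(1:3, function(i) make_fret(rnorm(60, 0.4, 0.05) + i / 100))
  m <- fit_hmm(fr, n_states = 1, seed = 1, n_restarts = 1)
  pool <- unlist(lapply(fr, fret_values))
  expect_equal(m$means, mean(pool), tolerance = 1e-12)
  expect_equal(m$transition_matrix, matrix(1, 1, 1))
})

test_that("EM log-likelihood is non-decreasing across iterations", {
  fr <- sim_corrected("IC2", 4, 21, duration = 60)
  m <- fit_hmm(fr, 3, seed = 1, n_restarts = 2)
  expect_true(all(diff(m$ll_trace) > -1e-6 * abs(m$log_likelihood)))
})

test_that("a two-state generator is recovered within stated tolerances", {
  sc <- two_state_scheme(k12 = 0.3, k21 = 0.3, e1 = 0.2, e2 = 0.6)
  ph <- fixture_photophysics("longmovie")
  prot <- protocol(500)
  traces <- simulate_traces(scheme = sc, phys = ph, protocol = prot,
                            n_traces = 10, seed = 3)
  traces <- suppressWarnings(
    subtract_direct_excitation(traces, global_offset = ph$direct_excitation))
  fr <- lapply(traces, compute_fret, params = correction_params(beta = 0.08))
  m <- fit_hmm(fr, n_states = 2, seed = 1)
  expect_equal(m$means, c(0.2, 0.6), tolerance = 0.01 / 0.2)
  p_true <- 0.3 * 0.1
  expect_equal(m$transition_matrix[1, 2], p_true, tolerance = 0.2)
  expect_equal(m$transition_matrix[2, 1], p_true, tolerance = 0.2)
})

test_that("Viterbi matches exhaustive enumeration on short traces", {
  set.seed(31)
  means <- c(0.15, 0.45, 0.8); sds <- c(0.08, 0.07, 0.09)
  A <- matrix(c(0.9, 0.07, 0.03,
                0.05, 0.9, 0.05,
                0.02, 0.08, 0.9), 3, 3, byrow = TRUE)
  pi <- c(0.3, 0.4, 0.3)
  model <- structure(list(n_states = 3, means = means, sds = sds,
                          transition_matrix = A, initial_probs = pi,
                          frame_interval = 0.1),
                     class = "hmm_model")
  for (rep in 1:5) {
    y <- runif(8, 0, 1)
    p <- viterbi(model, make_fret(y))
    bf <- brute_force_viterbi(y, means, sds, A, pi)
    lp_viterbi <- log(pi[p$states[1]]) +
      sum(dnorm(y, means[p$states], sds[p$states], log = TRUE)) +
      sum(log(A[cbind(p$states[-8], p$states[-1])]))
    expect_equal(lp_viterbi, bf$best, tolerance = 1e-10)
  }
})

test_that("noiseless traces at the state means decode exactly", {
  model <- structure(list(n_states = 2, means = c(0.2, 0.7),
                          sds = c(0.05, 0.05),
                          transition_matrix = matrix(c(0.95, 0.05,
                                                       0.05, 0.95), 2, 2),
                          initial_probs = c(0.5, 0.5),
                          frame_interval = 0.1),
                     class = "hmm_model")
  truth <- rep(c(1L, 2L, 1L), c(10, 15, 5))
  y <- c(0.2, 0.7)[truth]
  p <- viterbi(model, make_fret(y))
  expect_identical(p$states, truth)
  expect_equal(nrow(p$segments), 3)
  expect_true(all(diff(p$segments$state) != 0))   # no same-state adjacency
  single <- viterbi(model, make_fret(rep(0.7, 20)))
  expect_equal(nrow(single$segments), 1)
  empty <- viterbi(model, make_fret(numeric(0)))
  expect_equal(length(empty$states), 0)
})

test_that("pooled fit on duplicated data equals the fit on the original", {
  fr <- sim_corrected("IC0", 4, 22, duration = 80)
  m1 <- fit_hmm(fr, 2, seed = 5, n_restarts = 1)
  m2 <- fit_hmm(c(fr, fr), 2, seed = 5, n_restarts = 1)
  expect_equal(m1$means, m2$means, tolerance = 1e-6)
  expect_equal(m1$transition_matrix, m2$transition_matrix, tolerance = 1e-5)
})

test_that("decoded frame labels match the generator ground truth", {
  traces <- simulate_traces("IC2", n_traces = 10, seed = 23)
  traces <- subtract_direct_excitation(traces)
  fr <- lapply(traces, compute_fret, params = correction_params(beta = 0.08))
  m <- fit_hmm(fr, 3, seed = 1)
  acc <- mapply(function(tr, f) {
    truth <- attr(tr, "truth")$state[!f$masked]
    p <- viterbi(m, f)
    mean(p$states == truth)
  }, traces, fr)
  expect_gt(mean(acc), 0.95)
})

test_that("transition density concentrates at the state-level pairs", {
  traces <- simulate_traces("IC2", n_traces = 12, seed = 24)
  traces <- subtract_direct_excitation(traces)
  fr <- lapply(traces, compute_fret, params = correction_params(beta = 0.08))
  m <- fit_hmm(fr, 3, seed = 1)
  paths <- lapply(fr, function(f) viterbi(m, f))
  td <- transition_density(paths, fr)
  expect_gt(td$n_transitions, 50)
  expect_equal(sum(td$matrix), td$n_transitions)
  # dominant transitions join the open (0.376) and scrunched (0.563) levels
  edges <- td$bin_edges
  bin_of <- function(x) findInterval(x, edges)
  mid <- bin_of(0.376); hi <- bin_of(0.563)
  w <- 2   # +/- 2 bins
  block <- function(i, j) sum(td$matrix[(i - w):(i + w), (j - w):(j + w)])
  expect_gt((block(mid, hi) + block(hi, mid)) / td$n_transitions, 0.5)
  # single-segment paths contribute nothing
  empty <- transition_density(list(make_path(rep(1L, 50))), fr)
  expect_equal(empty$n_transitions, 0)
})

test_that("model-implied rates follow the embedded-chain formulas", {
  A <- matrix(c(1 - 0.0305, 0.0305, 0.02, 0.98), 2, 2, byrow = TRUE)
  model <- structure(list(n_states = 2, means = c(0.3, 0.6),
                          sds = c(0.05, 0.05), transition_matrix = A,
                          initial_probs = c(0.5, 0.5),
                          expected_transitions = A * 500,
                          frame_interval = 0.1),
                     class = "hmm_model")
  r <- rates_from_model(model)
  r12 <- r[r$from == 1 & r$to == 2, ]
  expect_equal(r12$rate, 0.305, tolerance = 1e-12)
  # exact 2-state inversion recovers the generator of P = expm(Q dt)
  Q <- matrix(c(-0.5, 0.5, 0.4, -0.4), 2, 2, byrow = TRUE)
  P <- pracma::expm(Q * 0.1)
  model$transition_matrix <- P
  model$expected_transitions <- P * 500
  r2 <- rates_from_model(model)
  expect_equal(r2$rate_exact[r2$from == 1 & r2$to == 2], 0.5,
               tolerance = 1e-5)
  expect_equal(r2$rate_exact[r2$from == 2 & r2$to == 1], 0.4,
               tolerance = 1e-5)
  # identity matrix: all rates zero
  model$transition_matrix <- diag(2)
  model$expected_transitions <- diag(2) * 500
  expect_true(all(rates_from_model(model)$rate == 0))
})
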