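# shared fixtures-in-code for the test suite

sim_corrected <- function(fixture, n, seed, duration = NULL,
                          variant = "default", beta = 0.08) {
  traces <- simulate_traces(fixture, n_traces = n, seed = seed,
                            duration = duration, phys_variant = variant)
  traces <- suppressWarnings(subtract_direct_excitation(traces))
  lapply(traces, compute_fret, params = correction_params(beta = beta))
}

make_trace <- function(donor, acceptor, ...) {
  intensity_trace("t1", seq_along(donor) * 0.1, donor, acceptor, ...)
}

make_fret <- function(e, dt = 0.1, id = "t1") {
  fret_trace(id, seq_along(e) * dt, e, masked = rep(FALSE, length(e)),
             params = correction_params(), frame_interval = dt)
}

make_path <- function(states, dt = 0.1, id = "t1") {
  r <- rle(states)
  ends <- cumsum(r$lengths)
  structure(list(trace_id = id, states = states,
                 segments = data.frame(state = r$values,
                                       start_frame = ends - r$lengths + 1L,
                                       end_frame = ends),
                 frame_interval = dt),
            class = "state_path")
}

two_state_scheme <- function(k12 = 1, k21 = 1, e1 = 0.2, e2 = 0.8,
                             sd = 0.08) {
  kinetic_scheme(
    states = data.frame(label = c("closed", "open"),
                        fret_mean = c(e1, e2), fret_sd = c(sd, sd)),
    rates = data.frame(from = c("closed", "open"), to = c("open", "closed"),
                       rate = c(k12, k21)))
}

occupancy_time <- function(traj, state) {
  seg_end <- c(traj$jump_times[-1], traj$t_end)
  sum((seg_end - traj$jump_times)[traj$state_sequence == state])
}
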