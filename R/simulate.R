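#' Exact stochastic simulation of a conformational kinetic scheme
#'
#' Samples a continuous-time Markov chain trajectory from a
#' [kinetic_scheme()] using the Gillespie direct method.  Rates are
#' piecewise-constant between [protocol()] events; at each event the
#' exponential clocks restart, which is exact for memoryless waiting times.
#'
#' @param scheme a [kinetic_scheme()].
#' @param protocol a [protocol()] defining duration and NTP-availability
#'   events.
#' @param seed integer seed; identical seeds give identical trajectories.
#' @param ntp0 named numeric vector of initial NTP availability factors
#'   (default: every species available at factor 1).
#' @param max_jumps safety cap on the number of transitions.
#' @return An object of class `state_trajectory` with fields `jump_times`
#'   (s, starting at 0), `state_sequence` (1-based state indices), `t_end`
#'   (s) and `states` (the scheme's state table, carried along for
#'   rendering).
#' @export
simulate_ctmc <- function(scheme, protocol, seed = NULL, ntp0 = NULL,
                          max_jumps = 1e6) {
  stop_if_not(inherits(scheme, "kinetic_scheme"), "scheme must be a kinetic_scheme")
  stop_if_not(inherits(protocol, "protocol"), "protocol must be a protocol")
  seed_stream(seed)

  K <- nrow(scheme$states)
  avail <- if (is.null(ntp0)) numeric(0) else ntp0
  ev <- protocol$events
  ev_times <- vapply(ev, function(e) as.numeric(e$time), numeric(1))
  duration <- protocol$duration

  s <- sample.int(K, 1, prob = scheme$initial)
  t <- 0
  jump_times <- numeric(64); state_seq <- integer(64)
  n <- 1L; jump_times[1] <- 0; state_seq[1] <- s

  apply_events_upto <- function(time) {
    while (length(ev_times) && ev_times[1] <= time) {
      e <- ev[[1]]
      if (!is.null(e$ntp)) {
        upd <- unlist(e$ntp)
        avail[names(upd)] <<- upd
      }
      ev <<- ev[-1]; ev_times <<- ev_times[-1]
    }
  }
  apply_events_upto(0)

  repeat {
    Q <- scheme_generator(scheme, if (length(avail)) avail else NULL)
    seg_end <- if (length(ev_times)) min(ev_times[1], duration) else duration
    repeat {
      R <- -Q[s, s]
      if (R <= 0) { t <- seg_end; break }
      tau <- rexp(1, R)
      if (t + tau >= seg_end) { t <- seg_end; break }
      t <- t + tau
      p <- Q[s, ]; p[s] <- 0
      s <- sample.int(K, 1, prob = p)
      n <- n + 1L
      if (n > length(jump_times)) {
        length(jump_times) <- 2 * length(jump_times)
        length(state_seq) <- 2 * length(state_seq)
      }
      jump_times[n] <- t; state_seq[n] <- s
      if (n >= max_jumps) stop("max_jumps exceeded in simulate_ctmc")
    }
    if (t >= duration) break
    apply_events_upto(t)
  }

  structure(list(jump_times = jump_times[seq_len(n)],
                 state_sequence = state_seq[seq_len(n)],
                 t_end = duration,
                 states = scheme$states),
            class = "state_trajectory")
}

#' Per-frame state occupancy of a trajectory
#'
#' Integrates the piecewise-constant state path over camera frames, giving
#' the exact occupancy-weighted fraction each state contributes to each
#' frame (camera integration, not midpoint snapshots).
#'
#' @param traj a `state_trajectory`.
#' @param frame_interval frame length (s).
#' @param window numeric `c(t0, t1)` sub-interval to frame; default the
#'   whole trajectory.
#' @return Matrix of `n_frames` x `n_states` occupancy fractions
#'   (rows sum to 1).
#' @export
frame_occupancy <- function(traj, frame_interval = 0.1, window = NULL) {
  dt <- frame_interval
  w0 <- if (is.null(window)) 0 else window[1]
  w1 <- if (is.null(window)) traj$t_end else window[2]
  n_frames <- floor((w1 - w0) / dt + 1e-9)
  K <- nrow(traj$states)
  occ <- matrix(0, n_frames, K)
  if (n_frames == 0) return(occ)
  seg_start <- traj$jump_times
  seg_end <- c(traj$jump_times[-1], traj$t_end)
  for (i in seq_along(seg_start)) {
    a <- max(seg_start[i], w0); b <- min(seg_end[i], w1)
    if (b <= a) next
    f0 <- floor((a - w0) / dt + 1e-9)
    f1 <- min(ceiling((b - w0) / dt - 1e-9) - 1, n_frames - 1)
    if (f1 < f0) next
    fr <- f0:f1
    ov <- pmin(b - w0, (fr + 1) * dt) - pmax(a - w0, fr * dt)
    k <- traj$state_sequence[i]
    occ[fr + 1, k] <- occ[fr + 1, k] + ov
  }
  occ / dt
}

# invert the apparent-E formula through the physical gamma/beta model:
# channels are I_D = Q (1 - Ephys), I_A = gamma Q Ephys + beta Q + direct,
# so that (I_A - beta I_D) / (I_D + I_A) after direct subtraction equals
# the apparent efficiency e exactly.
apparent_to_physical <- function(e, gamma, beta) {
  e * (1 + beta) / ((gamma + beta) - e * (gamma - 1))
}

#' Render a state trajectory into a two-colour intensity trace
#'
#' Forward photophysics model: the per-frame apparent FRET efficiency is
#' the occupancy-weighted mean of the state levels plus Gaussian
#' conformational noise; channel intensities combine the detection
#' asymmetry `gamma`, donor leakage `beta` (a constant fraction of the
#' donor excitation budget while the donor is alive), acceptor direct
#' excitation, Gaussian background and Poisson shot noise.  Each dye
#' bleaches at most once (exponential times under illumination).  After
#' donor bleaching the acceptor channel carries only direct excitation and
#' background; after acceptor bleaching the donor recovers the full photon
#' budget and the acceptor channel carries only leakage.
#'
#' Applying the correction pipeline with the true (beta, gamma, direct
#' excitation) recovers each state's `fret_mean` without bias; in the
#' noiseless limit the recovery is exact.
#'
#' @param traj a `state_trajectory` from [simulate_ctmc()].
#' @param phys a [photophysics()] object.
#' @param seed integer seed.
#' @param frame_interval frame length (s), default 0.1.
#' @param window `c(t0, t1)` to render a sub-interval (a "short movie");
#'   bleaching clocks start at the window start, when illumination begins.
#' @param noiseless if `TRUE`, emit expected intensities with no shot
#'   noise, background or state noise, and no photobleaching
#'   (infinite-photon limit).
#' @param acceptor_present if `FALSE`, render a donor-only molecule
#'   (no energy transfer, no direct excitation).
#' @param single_pair metadata flag carried into the trace.
#' @param trace_id identifier string.
#' @return An `intensity_trace`: per-frame `time`, `donor`, `acceptor`
#'   photon counts plus bleach/illumination metadata.  Ground truth
#'   (state path, true apparent E per frame) is attached as
#'   `attr(, "truth")`.
#' @export
render_trace <- function(traj, phys, seed = NULL, frame_interval = 0.1,
                         window = NULL, noiseless = FALSE,
                         acceptor_present = TRUE, single_pair = TRUE,
                         trace_id = "trace_1") {
  stop_if_not(inherits(phys, "photophysics"),
              "phys must be a photophysics object (negative parameters are rejected by its constructor)")
  stop_if_not(frame_interval > 0, "frame_interval must be > 0")
  seed_stream(seed)
  dt <- frame_interval
  w0 <- if (is.null(window)) 0 else window[1]
  occ <- frame_occupancy(traj, dt, window)
  n_frames <- nrow(occ)
  stop_if_not(n_frames > 0, "window shorter than one frame")

  fm <- traj$states$fret_mean
  fv <- traj$states$fret_sd^2
  e_true <- as.numeric(occ %*% fm)
  v_true <- as.numeric(occ %*% fv)
  true_state <- max.col(occ, ties.method = "first")

  e_app <- if (noiseless) e_true else e_true + rnorm(n_frames, 0, sqrt(v_true))

  g <- phys$gamma; b <- phys$beta; Q <- phys$total_rate
  d <- phys$direct_excitation

  if (noiseless) {
    t_d <- Inf; t_a <- Inf
  } else {
    t_d <- if (phys$donor_bleach_rate > 0) rexp(1, phys$donor_bleach_rate) else Inf
    t_a <- if (acceptor_present && phys$acceptor_bleach_rate > 0)
      rexp(1, phys$acceptor_bleach_rate) else Inf
  }
  donor_bleach <- if (is.finite(t_d) && t_d < n_frames * dt)
    floor(t_d / dt) + 1L else NA_integer_
  acceptor_bleach <- if (is.finite(t_a) && t_a < n_frames * dt)
    floor(t_a / dt) + 1L else NA_integer_

  fr <- seq_len(n_frames)
  d_alive <- if (is.na(donor_bleach)) rep(TRUE, n_frames) else fr < donor_bleach
  a_alive <- if (!acceptor_present) rep(FALSE, n_frames) else
    if (is.na(acceptor_bleach)) rep(TRUE, n_frames) else fr < acceptor_bleach

  e_phys <- apparent_to_physical(e_app, g, b)
  lamD <- numeric(n_frames); lamA <- numeric(n_frames)
  both <- d_alive & a_alive
  lamD[both] <- Q * (1 - e_phys[both])
  lamA[both] <- g * Q * e_phys[both] + b * Q + d
  donly <- d_alive & !a_alive           # acceptor bleached or absent
  lamD[donly] <- Q
  lamA[donly] <- b * Q
  aonly <- !d_alive & a_alive           # donor bleached first
  lamA[aonly] <- d
  lamD <- pmax(lamD, 0); lamA <- pmax(lamA, 0)

  if (noiseless) {
    donor <- lamD; acceptor <- lamA
  } else {
    donor <- rpois(n_frames, lamD) + rnorm(n_frames, 0, phys$background_sd)
    acceptor <- rpois(n_frames, lamA) + rnorm(n_frames, 0, phys$background_sd)
  }

  tr <- intensity_trace(trace_id = trace_id,
                        time = w0 + (fr - 1) * dt,
                        donor = donor, acceptor = acceptor,
                        donor_bleach_frame = donor_bleach,
                        acceptor_bleach_frame = acceptor_bleach,
                        acceptor_present = acceptor_present,
                        single_pair = single_pair,
                        frame_interval = dt)
  attr(tr, "truth") <- list(e_app = e_true, state = true_state,
                            state_label = traj$states$label[true_state],
                            direct = if (acceptor_present) d else 0,
                            donor_bleach_frame = donor_bleach,
                            acceptor_bleach_frame = acceptor_bleach,
                            jump_times = traj$jump_times,
                            state_sequence = traj$state_sequence)
  tr
}

#' Simulate a batch of intensity traces from a scheme or packaged fixture
#'
#' Convenience wrapper chaining [simulate_ctmc()] and [render_trace()] for
#' `n_traces` molecules under one seed (a single random stream).
#'
#' @param fixture name of a packaged fixture (see [fixtures()]); mutually
#'   exclusive with `scheme`/`phys`/`protocol`.
#' @param scheme,phys,protocol explicit objects overriding (or replacing)
#'   the fixture's.
#' @param n_traces number of molecules.
#' @param seed integer seed for the whole batch.
#' @param duration optional override of the protocol duration (s).
#' @param single_pair_fraction fraction of traces flagged as carrying a
#'   single donor-acceptor pair (the remainder is flagged multi-pair for
#'   filtering studies).
#' @param acceptor_fraction fraction of traces with an acceptor dye.
#' @param noiseless passed to [render_trace()].
#' @param phys_variant packaged photophysics variant used when `fixture`
#'   is given (`"default"`, `"longmovie"`, `"nobleach"`).
#' @return List of `intensity_trace` objects.
#' @export
simulate_traces <- function(fixture = NULL, scheme = NULL, phys = NULL,
                            protocol = NULL, n_traces = 100, seed = 1,
                            duration = NULL, single_pair_fraction = 1,
                            acceptor_fraction = 1, noiseless = FALSE,
                            phys_variant = "default") {
  if (!is.null(fixture)) {
    fx <- fixtures(fixture, phys = phys_variant)
    scheme <- scheme %||% fx$scheme
    phys <- phys %||% fx$phys
    protocol <- protocol %||% fx$protocol
  }
  stop_if_not(!is.null(scheme) && !is.null(phys) && !is.null(protocol),
              "provide a fixture name or scheme + phys + protocol")
  if (!is.null(duration))
    protocol <- protocol(duration, protocol$frame_interval, protocol$events)
  seed_stream(seed)
  sp <- runif(n_traces) <= single_pair_fraction
  ap <- runif(n_traces) <= acceptor_fraction
  lapply(seq_len(n_traces), function(i) {
    traj <- simulate_ctmc(scheme, protocol)
    render_trace(traj, phys, frame_interval = protocol$frame_interval,
                 noiseless = noiseless, acceptor_present = ap[i],
                 single_pair = sp[i],
                 trace_id = sprintf("trace_%04d", i))
  })
}

#' Simulate an ensemble 2-aminopurine fluorescence decay
#'
#' Generates `F(t) = f_inf + (f0 - f_inf) exp(-k t)` plus Gaussian noise,
#' the single-exponential bubble-collapse signal measured in the 2AP
#' quenching assay.  `f0 < f_inf` gives a rising exponential and is
#' allowed.
#'
#' @param k decay rate (s^-1, >= 0).
#' @param f0 initial fluorescence (a.u.).
#' @param f_inf plateau fluorescence (a.u.).
#' @param duration time span (s).
#' @param noise_sd Gaussian noise amplitude (a.u.).
#' @param seed integer seed.
#' @param dt sampling interval (s).
#' @return data.frame with columns `time` and `value`.
#' @export
simulate_2ap_decay <- function(k, f0, f_inf, duration, noise_sd = 0,
                               seed = NULL, dt = 1) {
  stop_if_not(is.numeric(k) && k >= 0, "k must be >= 0")
  stop_if_not(duration > 0, "duration must be > 0")
  seed_stream(seed)
  tt <- seq(0, duration, by = dt)
  f <- f_inf + (f0 - f_inf) * exp(-k * tt)
  if (noise_sd > 0) f <- f + rnorm(length(tt), 0, noise_sd)
  data.frame(time = tt, value = f)
}

#' Simulate per-minute short movies after NTP washout
#'
#' Emulates the washout imaging protocol: the population evolves from the
#' washout at t = 0 under the fixture's post-washout scheme, and during
#' each minute a set of short movies of fresh fields of view is recorded.
#' Each movie images molecules whose conformational history started at the
#' washout; illumination (and hence photobleaching) starts at the movie
#' start.
#'
#' @param fixture packaged fixture name (e.g. `"washout_IC7"`).
#' @param minutes number of minutes to cover (movies for minute `m` start
#'   at `60 m + offsets`).
#' @param movies_per_minute short movies per minute (default 12).
#' @param traces_per_movie molecules per movie.
#' @param movie_length movie duration (s).
#' @param seed integer seed.
#' @param phys_variant packaged photophysics variant.
#' @return List with one element per minute: `list(minute =, traces =)`.
#' @export
simulate_washout_series <- function(fixture, minutes = 12,
                                    movies_per_minute = 12,
                                    traces_per_movie = 17,
                                    movie_length = 5, seed = 1,
                                    phys_variant = "default") {
  fx <- fixtures(fixture, phys = phys_variant)
  dt <- fx$protocol$frame_interval
  seed_stream(seed)
  lapply(seq_len(minutes) - 1L, function(m) {
    traces <- list()
    for (j in seq_len(movies_per_minute)) {
      t0 <- m * 60 + (j - 1) * 60 / movies_per_minute
      prot <- protocol(t0 + movie_length, dt)
      for (i in seq_len(traces_per_movie)) {
        traj <- simulate_ctmc(fx$scheme, prot)
        traces[[length(traces) + 1]] <-
          render_trace(traj, fx$phys, frame_interval = dt,
                       window = c(t0, t0 + movie_length),
                       trace_id = sprintf("min%02d_mov%02d_tr%03d", m, j, i))
      }
    }
    list(minute = m, traces = traces)
  })
}
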