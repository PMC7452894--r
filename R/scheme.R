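#' Conformational kinetic scheme
#'
#' A `kinetic_scheme` describes the conformational states of a transcription
#' complex (closed, open, scrunched, backtracked, elongation, or bare DNA),
#' the apparent FRET efficiency each state emits, and the first-order rate
#' constants connecting them.  Transitions that consume nucleotides can be
#' tagged with an NTP species; a [protocol()] can then switch those rates on
#' and off mid-recording (flow-in / washout experiments).
#'
#' @param states data.frame with columns `label` (character), `fret_mean`
#'   (apparent FRET efficiency, in `[0, 1]`) and `fret_sd` (per-frame
#'   conformational broadening of the FRET signal).
#' @param rates data.frame with columns `from`, `to` (state labels), `rate`
#'   (s^-1, non-negative) and optionally `ntp` (character species tag, `NA`
#'   for NTP-independent transitions).  `NULL` means no transitions.
#' @param initial numeric vector of initial-state probabilities, summing to
#'   one; recycled to uniform when `NULL`.
#' @return An object of class `kinetic_scheme`.
#' @examples
#' sc <- kinetic_scheme(
#'   states = data.frame(label = c("closed", "open"),
#'                       fret_mean = c(0.135, 0.376),
#'                       fret_sd = c(0.08, 0.08)),
#'   rates = data.frame(from = "closed", to = "open", rate = 0.3))
#' @export
kinetic_scheme <- function(states, rates = NULL, initial = NULL) {
  stop_if_not(is.data.frame(states) &&
                all(c("label", "fret_mean", "fret_sd") %in% names(states)),
              "'states' needs columns label, fret_mean, fret_sd")
  states$label <- as.character(states$label)
  stop_if_not(!anyDuplicated(states$label), "duplicate state labels")
  stop_if_not(all(states$fret_mean >= 0 & states$fret_mean <= 1),
              "fret_mean must lie in [0, 1]")
  stop_if_not(all(states$fret_sd >= 0), "fret_sd must be non-negative")
  K <- nrow(states)

  if (is.null(rates) || (is.data.frame(rates) && nrow(rates) == 0)) {
    rates <- data.frame(from = character(), to = character(),
                        rate = numeric(), ntp = character(),
                        stringsAsFactors = FALSE)
  }
  stop_if_not(all(c("from", "to", "rate") %in% names(rates)),
              "'rates' needs columns from, to, rate")
  if (is.null(rates$ntp)) rates$ntp <- rep(NA_character_, nrow(rates))
  rates$from <- as.character(rates$from)
  rates$to   <- as.character(rates$to)
  rates$ntp  <- as.character(rates$ntp)
  stop_if_not(all(rates$from %in% states$label) &&
                all(rates$to %in% states$label),
              "rate endpoints must be declared states")
  stop_if_not(all(rates$rate >= 0), "rates must be non-negative")
  stop_if_not(!any(rates$from == rates$to), "self-transitions are not allowed")

  if (is.null(initial)) initial <- rep(1 / K, K)
  stop_if_not(length(initial) == K && all(initial >= 0) &&
                abs(sum(initial) - 1) <= 1e-12,
              "initial distribution must have one probability per state and sum to 1")

  structure(list(states = states, rates = rates,
                 initial = as.numeric(initial)),
            class = "kinetic_scheme")
}

#' @export
print.kinetic_scheme <- function(x, ...) {
  cat("Kinetic scheme:", nrow(x$states), "states,",
      nrow(x$rates), "transitions\n")
  print(x$states, row.names = FALSE)
  if (nrow(x$rates)) print(x$rates, row.names = FALSE)
  invisible(x)
}

#' Look up a single transition rate
#'
#' @param scheme a [kinetic_scheme()].
#' @param from,to state labels.
#' @return The base rate in s^-1 (0 when the transition is absent).
#' @export
scheme_rate <- function(scheme, from, to) {
  i <- scheme$rates$from == from & scheme$rates$to == to
  if (!any(i)) 0 else scheme$rates$rate[which(i)[1]]
}

#' State FRET mean of a scheme
#'
#' @param scheme a [kinetic_scheme()].
#' @param label state label.
#' @return Apparent FRET efficiency of the state.
#' @export
scheme_fret_mean <- function(scheme, label) {
  i <- match(label, scheme$states$label)
  stop_if_not(!is.na(i), paste0("unknown state '", label, "'"))
  scheme$states$fret_mean[i]
}

#' Rate generator matrix under a given NTP availability
#'
#' Builds the continuous-time generator Q of the scheme, multiplying every
#' NTP-tagged transition by the availability factor of its species
#' (1 when the species is not listed).
#'
#' @param scheme a [kinetic_scheme()].
#' @param ntp named numeric vector of availability factors per species
#'   (e.g. `c(NTP = 0)` after washout); `NULL` for full availability.
#' @return K x K generator matrix (rows sum to zero).
#' @export
scheme_generator <- function(scheme, ntp = NULL) {
  K <- nrow(scheme$states)
  Q <- matrix(0, K, K, dimnames = list(scheme$states$label,
                                       scheme$states$label))
  for (r in seq_len(nrow(scheme$rates))) {
    rate <- scheme$rates$rate[r]
    sp <- scheme$rates$ntp[r]
    if (!is.na(sp) && !is.null(ntp) && sp %in% names(ntp))
      rate <- rate * ntp[[sp]]
    Q[scheme$rates$from[r], scheme$rates$to[r]] <- rate
  }
  diag(Q) <- -rowSums(Q)
  Q
}

#' Recording protocol with buffer-exchange events
#'
#' Events change NTP availability factors at fixed times, realizing
#' flow-in and washout experiments as piecewise-constant rate matrices.
#'
#' @param duration recording length (s).
#' @param frame_interval camera integration time per frame (s); the default
#'   0.1 matches 100 ms frames.
#' @param events list of `list(time =, ntp = c(species = factor))` entries
#'   with strictly increasing times inside `[0, duration]`.
#' @return An object of class `protocol`.
#' @export
protocol <- function(duration, frame_interval = 0.1, events = list()) {
  stop_if_not(is_count(duration) && duration > 0, "duration must be > 0")
  stop_if_not(is_count(frame_interval) && frame_interval > 0,
              "frame_interval must be > 0")
  times <- vapply(events, function(e) as.numeric(e$time), numeric(1))
  if (length(times)) {
    stop_if_not(all(diff(times) > 0), "event times must be strictly increasing")
    stop_if_not(all(times >= 0 & times <= duration),
                "event times must lie within [0, duration]")
  }
  structure(list(duration = duration, frame_interval = frame_interval,
                 events = events),
            class = "protocol")
}

#' Photophysical parameters of the donor-acceptor pair
#'
#' @param total_rate detected photon budget per frame for an unbleached
#'   pair (photons/frame).
#' @param gamma detection-efficiency / quantum-yield ratio between acceptor
#'   and donor channels (default 1.51, the value measured for this setup).
#' @param beta donor leakage fraction into the acceptor channel
#'   (default 0.08).
#' @param direct_excitation acceptor photons/frame excited directly by the
#'   green laser.
#' @param background_sd Gaussian background noise per channel
#'   (photons/frame).
#' @param donor_bleach_rate,acceptor_bleach_rate single-step irreversible
#'   photobleaching rates (s^-1) under illumination.
#' @return An object of class `photophysics`.
#' @export
photophysics <- function(total_rate = 1000, gamma = 1.51, beta = 0.08,
                         direct_excitation = 80, background_sd = 15,
                         donor_bleach_rate = 0.004,
                         acceptor_bleach_rate = 0.02) {
  vals <- c(total_rate, gamma, beta, direct_excitation, background_sd,
            donor_bleach_rate, acceptor_bleach_rate)
  stop_if_not(all(is.finite(vals)) && all(vals >= 0),
              "all photophysics parameters must be finite and non-negative")
  stop_if_not(beta < 1, "beta must be < 1")
  structure(list(total_rate = total_rate, gamma = gamma, beta = beta,
                 direct_excitation = direct_excitation,
                 background_sd = background_sd,
                 donor_bleach_rate = donor_bleach_rate,
                 acceptor_bleach_rate = acceptor_bleach_rate),
            class = "photophysics")
}
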