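#' Subtract acceptor direct excitation
#'
#' The green laser weakly excites the acceptor directly; the resulting
#' offset is estimated per trace as the mean acceptor intensity after donor
#' photobleaching (while the acceptor is still alive) and subtracted from
#' all frames recorded with a live acceptor.  Traces without a usable
#' post-donor-bleach window fall back to the median offset across the
#' movie and are flagged (`direct_fallback`).
#'
#' @param traces a single [intensity_trace()] or a list of them.
#' @param min_post_frames minimum usable post-bleach frames for a
#'   per-trace estimate (default 10).
#' @param global_offset offset to use for fallback traces; defaults to the
#'   median of the per-trace estimates in the batch.
#' @return Corrected trace(s) of the same shape, with `direct_offset`
#'   recorded on each trace.
#' @export
subtract_direct_excitation <- function(traces, min_post_frames = 10,
                                       global_offset = NULL) {
  single <- inherits(traces, "intensity_trace")
  if (single) traces <- list(traces)

  est_one <- function(tr) {
    db <- tr$donor_bleach_frame
    if (is.na(db)) return(NA_real_)
    last <- if (is.na(tr$acceptor_bleach_frame)) n_frames(tr)
            else tr$acceptor_bleach_frame - 1L
    if (last - db + 1L < min_post_frames) return(NA_real_)
    mean(tr$acceptor[db:last])
  }
  offsets <- vapply(traces, est_one, numeric(1))
  fallback <- is.na(offsets)
  if (any(fallback)) {
    gl <- global_offset %||%
      (if (all(fallback)) 0 else median(offsets[!fallback]))
    if (is.null(global_offset) && all(is.na(offsets)))
      warning("no trace had a usable post-donor-bleach window; direct offset 0 applied")
    offsets[fallback] <- gl
  }
  out <- mapply(function(tr, off, fb) {
    live <- if (is.na(tr$acceptor_bleach_frame)) seq_len(n_frames(tr))
            else seq_len(tr$acceptor_bleach_frame - 1L)
    if (tr$acceptor_present && length(live))
      tr$acceptor[live] <- tr$acceptor[live] - off
    tr$direct_offset <- off
    tr$direct_fallback <- fb
    tr
  }, traces, offsets, fallback, SIMPLIFY = FALSE)
  if (single) out[[1]] else out
}

masked_frames <- function(trace) {
  n <- n_frames(trace)
  m <- rep(FALSE, n)
  first_bleach <- suppressWarnings(
    min(trace$donor_bleach_frame, trace$acceptor_bleach_frame, na.rm = TRUE))
  if (is.finite(first_bleach)) m[seq_len(n) >= first_bleach] <- TRUE
  m
}

#' Apparent FRET efficiency of a trace
#'
#' Computes `E = (I_A - beta I_D) / (I_D + I_A)` per frame, after direct
#' excitation has been subtracted (see
#' [subtract_direct_excitation()]).  Frames after either photobleaching
#' event are masked, as are frames with non-positive total intensity
#' (masked, never NaN-propagated).
#'
#' @param trace an [intensity_trace()].
#' @param params a [correction_params()].
#' @return A [fret_trace()].
#' @export
compute_fret <- function(trace, params) {
  stop_if_not(inherits(params, "correction_params"),
              "params must be correction_params")
  D <- trace$donor; A <- trace$acceptor
  tot <- D + A
  m <- masked_frames(trace) | !(tot > 0)
  e <- rep(NA_real_, length(D))
  e[!m] <- (A[!m] - params$beta * D[!m]) / tot[!m]
  fret_trace(trace$trace_id, trace$time, e, m, params,
             gamma_corrected = FALSE, frame_interval = trace$frame_interval)
}

#' Gamma-corrected FRET efficiency of a trace
#'
#' Implements the correction exactly as used for distance estimation:
#' `E = (I_A - beta I_D) / (gamma (I_D + beta I_D) + I_A - beta I_D)`.
#' With `gamma = 1` the denominator reduces algebraically to
#' `I_D + I_A`, i.e. the apparent-E formula.  The denominator term
#' `gamma (I_D + beta I_D)` differs from the more common
#' `gamma I_D` convention; `conventional = TRUE` switches to
#' `gamma I_D + I_A - beta I_D`.
#'
#' @param trace an [intensity_trace()] (direct excitation already
#'   subtracted).
#' @param params a [correction_params()] with `gamma` set.
#' @param conventional use the `gamma I_D` denominator instead of the
#'   default `gamma (I_D + beta I_D)`.
#' @return A [fret_trace()] with `gamma_corrected = TRUE`.
#' @export
compute_fret_gamma <- function(trace, params, conventional = FALSE) {
  stop_if_not(inherits(params, "correction_params"),
              "params must be correction_params")
  stop_if_not(!is.na(params$gamma) && params$gamma > 0,
              "gamma must be set and > 0")
  D <- trace$donor; A <- trace$acceptor
  num <- A - params$beta * D
  den <- if (conventional) params$gamma * D + num
         else params$gamma * (D + params$beta * D) + num
  m <- masked_frames(trace) | !(D + A > 0) | !(den != 0)
  e <- rep(NA_real_, length(D))
  e[!m] <- num[!m] / den[!m]
  fret_trace(trace$trace_id, trace$time, e, m, params,
             gamma_corrected = TRUE, frame_interval = trace$frame_interval)
}

#' Estimate the gamma factor from acceptor-photobleaching steps
#'
#' For every trace in which the acceptor bleaches while the donor
#' survives, gamma is the ratio of the acceptor intensity drop to the
#' donor intensity rise across the bleach step (window means on both
#' sides).  Direct excitation must be subtracted first, otherwise its loss
#' at the bleach inflates the acceptor step.  Events with steps below
#' `min_step` (e.g. no-FRET molecules) are excluded.  The estimate is the
#' median across events, with a bootstrap standard error.
#'
#' @param traces list of [intensity_trace()] objects.
#' @param window frames averaged on each side of the step (default 10).
#' @param min_step minimum donor rise and acceptor drop (photons/frame).
#' @param n_boot bootstrap replicates for the standard error.
#' @param seed seed for the bootstrap.
#' @return List with `gamma`, `se`, `n_events` and the per-event ratios.
#' @export
estimate_gamma <- function(traces, window = 10, min_step = 20,
                           n_boot = 200, seed = 1) {
  events <- unlist(lapply(traces, function(tr) {
    ab <- tr$acceptor_bleach_frame
    if (is.na(ab)) return(NULL)
    db <- tr$donor_bleach_frame
    n <- n_frames(tr)
    hi <- min(if (is.na(db)) n else db - 1L, ab + window - 1L)
    if (ab - window < 1L || hi < ab + window - 1L) return(NULL)
    pre <- (ab - window):(ab - 1L)
    post <- ab:(ab + window - 1L)
    dA <- mean(tr$acceptor[pre]) - mean(tr$acceptor[post])
    dD <- mean(tr$donor[post]) - mean(tr$donor[pre])
    if (!is.finite(dA) || !is.finite(dD)) return(NULL)
    if (dA < min_step || dD < min_step) return(NULL)
    dA / dD
  }))
  if (length(events) == 0)
    stop("no usable acceptor-photobleaching events; supply gamma manually",
         call. = FALSE)
  seed_stream(seed)
  g <- median(events)
  se <- if (length(events) > 1) {
    boots <- vapply(seq_len(n_boot), function(i)
      median(sample(events, replace = TRUE)), numeric(1))
    sd(boots)
  } else NA_real_
  list(gamma = g, se = se, n_events = length(events), events = events)
}

#' Estimate the donor-leakage fraction beta from donor-only molecules
#'
#' On molecules without an acceptor, every acceptor-channel photon above
#' background is leakage, so `beta = I_A / I_D` frame by frame.  The
#' per-trace median ratios are aggregated as the mode of their kernel
#' density.  The resulting beta centres the corrected donor-only FRET
#' peak at zero; the uncorrected peak sits at `beta / (1 + beta)`.
#'
#' @param donor_only_traces list of traces flagged
#'   `acceptor_present = FALSE`.
#' @param min_donor minimum donor intensity for a frame to enter the ratio
#'   (suppresses ratio blow-up on dim frames).
#' @return List with `beta`, `per_trace` medians and `n_traces`.
#' @export
estimate_beta <- function(donor_only_traces, min_donor = 50) {
  donor_only_traces <- Filter(function(tr) !tr$acceptor_present,
                              donor_only_traces)
  if (length(donor_only_traces) == 0)
    stop("no donor-only traces; flag traces with acceptor_present = FALSE ",
         "or supply beta manually", call. = FALSE)
  per_trace <- vapply(donor_only_traces, function(tr) {
    keep <- !masked_frames(tr) & tr$donor > min_donor
    if (!any(keep)) return(NA_real_)
    median(tr$acceptor[keep] / tr$donor[keep])
  }, numeric(1))
  per_trace <- per_trace[is.finite(per_trace)]
  stop_if_not(length(per_trace) > 0, "no usable donor-only frames")
  b <- if (length(per_trace) >= 10) {
    d <- density(per_trace)
    d$x[which.max(d$y)]
  } else median(per_trace)
  list(beta = max(b, 0), per_trace = per_trace,
       n_traces = length(per_trace))
}

#' Filter traces on acceptor presence and single-pair labelling
#'
#' Keeps traces confirmed to carry an acceptor dye (red-laser check) and a
#' single donor-acceptor pair, reporting counts per criterion.
#'
#' @param traces list of [intensity_trace()] objects.
#' @return List with `traces` (retained subset) and `report` (counts and
#'   fractions).
#' @export
filter_traces <- function(traces) {
  n <- length(traces)
  has_acc <- vapply(traces, function(tr) tr$acceptor_present, logical(1))
  single <- vapply(traces, function(tr) tr$single_pair, logical(1))
  keep <- has_acc & single
  report <- list(n_input = n,
                 n_no_acceptor = sum(!has_acc),
                 n_multi_pair = sum(has_acc & !single),
                 n_retained = sum(keep),
                 fraction_retained = if (n) sum(keep) / n else NA_real_,
                 empty_input = n == 0)
  list(traces = traces[keep], report = report)
}

#' Block-average FRET values for histogramming
#'
#' Averages consecutive non-overlapping blocks of `n` unmasked frames, one
#' value per block (five-frame averaging by default, as used to build the
#' FRET histograms); the trailing partial block is dropped.
#'
#' @param fret a [fret_trace()].
#' @param n frames per block (>= 1).
#' @return Numeric vector of block means (length 0 when the trace has
#'   fewer than `n` usable frames).
#' @export
block_average <- function(fret, n = 5) {
  stop_if_not(is_count(n) && n >= 1, "n must be >= 1")
  e <- fret_values(fret)
  nb <- floor(length(e) / n)
  if (nb == 0) return(numeric(0))
  colMeans(matrix(e[seq_len(nb * n)], nrow = n))
}
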