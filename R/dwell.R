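#' Harvest dwell times from decoded state paths
#'
#' Collects the durations of visits to `from_state`.  The first and last
#' segments of every trace are censored (excluded but counted): their
#' start or end is not observed.  Dwells shorter than two frames are kept
#' but counted as resolution-limited.
#'
#' @param paths list of [viterbi()] results.
#' @param from_state 1-based state index whose dwells are harvested.
#' @param to_state optional destination state; when given, only dwells
#'   ending in a transition to that state are kept.
#' @param n_states number of states of the model (for validation).
#' @param condition provenance label.
#' @return An object of class `dwell_set`: `dwells` (s),
#'   `censored_first`/`censored_last` counts, `n_short` (below two
#'   frames), `frame_interval`.
#' @export
extract_dwells <- function(paths, from_state, to_state = NULL,
                           n_states = NULL, condition = NULL) {
  K <- n_states %||% max(vapply(paths, function(p)
    if (length(p$states)) max(p$states) else 0L, integer(1)))
  stop_if_not(from_state >= 1 && from_state <= K,
              paste0("unknown state ", from_state, " (model has ", K, ")"))
  if (!is.null(to_state))
    stop_if_not(to_state >= 1 && to_state <= K,
                paste0("unknown state ", to_state, " (model has ", K, ")"))
  dt <- paths[[1]]$frame_interval
  dwells <- numeric(0)
  cf <- 0L; cl <- 0L
  for (p in paths) {
    seg <- p$segments
    ns <- nrow(seg)
    if (ns == 0) next
    if (seg$state[1] == from_state) cf <- cf + 1L
    if (seg$state[ns] == from_state && ns > 1) cl <- cl + 1L
    if (ns <= 2) next
    for (i in 2:(ns - 1)) {
      if (seg$state[i] != from_state) next
      if (!is.null(to_state) && seg$state[i + 1] != to_state) next
      dwells <- c(dwells, (seg$end_frame[i] - seg$start_frame[i] + 1) * dt)
    }
  }
  structure(list(condition = condition,
                 transition = paste0(from_state, "->",
                                     if (is.null(to_state)) "any" else to_state),
                 dwells = dwells, censored_first = cf, censored_last = cl,
                 n_short = sum(dwells < 2 * dt),
                 frame_interval = dt),
            class = "dwell_set")
}

two_exp_loglik <- function(par, d) {
  w <- 1 / (1 + exp(-par[1]))
  k1 <- exp(par[2]); k2 <- exp(par[3])
  sum(log(w * k1 * exp(-k1 * d) + (1 - w) * k2 * exp(-k2 * d)))
}

#' Transition rate from a dwell-time set
#'
#' The headline estimator is the inverse of the mean dwell time with
#' standard error `k / sqrt(n)` (identical to the exponential maximum
#' likelihood estimate).  A two-exponential mixture is also fitted and a
#' likelihood-ratio statistic reported, flagging non-exponential dwell
#' distributions (e.g. a mixture of states within the scrunched
#' conformation).
#'
#' @param dwells a [extract_dwells()] result.
#' @param min_n minimum number of usable dwells (default 10).
#' @return List with `rate` (s^-1), `se`, `n`, `mean_dwell`, the
#'   two-exponential fit (`two_exp`), `lr_stat` and `nonexponential`
#'   (likelihood-ratio statistic above the 1% chi-square(2) point).
#' @export
rate_from_dwells <- function(dwells, min_n = 10) {
  d <- dwells$dwells
  if (length(d) < min_n)
    stop("only ", length(d), " usable dwells (need >= ", min_n, ")",
         call. = FALSE)
  k <- 1 / mean(d)
  ll1 <- sum(log(k) - k * d)
  fit2 <- tryCatch(
    optim(c(0, log(k * 3), log(k / 3)), two_exp_loglik, d = d,
          control = list(fnscale = -1, maxit = 500)),
    error = function(e) NULL)
  if (!is.null(fit2)) {
    lr <- 2 * (fit2$value - ll1)
    two_exp <- list(w = 1 / (1 + exp(-fit2$par[1])),
                    k1 = exp(fit2$par[2]), k2 = exp(fit2$par[3]),
                    loglik = fit2$value)
  } else {
    lr <- NA_real_; two_exp <- NULL
  }
  list(rate = k, se = k / sqrt(length(d)), n = length(d),
       mean_dwell = mean(d), loglik_exp = ll1,
       two_exp = two_exp, lr_stat = lr,
       nonexponential = isTRUE(lr > 9.21))
}

impose_resolution <- function(path, resolution_frames) {
  if (length(path$states) == 0 || resolution_frames <= 1) return(path)
  s <- filter_short_runs(path$states, resolution_frames)
  r <- rle(s)
  ends <- cumsum(r$lengths)
  path$states <- s
  path$segments <- data.frame(state = r$values,
                              start_frame = ends - r$lengths + 1L,
                              end_frame = ends)
  path
}

# excursions out of `state` on a (resolution-filtered) path list:
# durations of returning excursions plus the count of exits that never
# return within the trace
collect_excursions <- function(fpaths, state, dt) {
  exc <- numeric(0); n_ret <- 0L; n_noret <- 0L
  for (p in fpaths) {
    seg <- p$segments
    ns <- nrow(seg)
    if (ns < 2) next
    at <- which(seg$state == state)
    at <- at[at < ns]
    for (i in at) {
      nxt <- which(seg$state == state & seq_len(ns) > i)
      nxt <- if (length(nxt)) nxt[1] else NA_integer_
      if (is.na(nxt)) { n_noret <- n_noret + 1L; next }
      n_ret <- n_ret + 1L
      exc <- c(exc, (seg$end_frame[nxt - 1L] - seg$start_frame[i + 1L] + 1L) * dt)
    }
  }
  list(exc = exc, n_ret = n_ret, n_noret = n_noret)
}

# exponential rate on a doubly truncated window [a, b] by moment matching
truncated_exp_rate <- function(x, a, b) {
  m <- mean(x)
  fm <- function(k) {
    w <- b - a
    1 / k + a - w * exp(-k * w) / (1 - exp(-k * w)) - m
  }
  if (fm(1e-3) * fm(50) > 0) return(1 / max(m - a, 1e-3))
  stats::uniroot(fm, c(1e-3, 50))$root
}

#' Dwell-based transition rate with missed-event correction
#'
#' Inverse-mean dwell rate of `state` from decoded paths, corrected for
#' the finite time resolution of camera-based recordings.  A fixed
#' resolution of `resolution_frames` frames is imposed on every path
#' (shorter visits are merged away), so the set of missed events is well
#' defined rather than an accident of decoding.  Under an alternating
#' renewal model with exponential sojourns, an observed dwell starts
#' with a visit conditioned to exceed the resolution `t_res` and is
#' extended by every sub-resolution excursion that returns, so its mean
#' is `mean(D)/(1-q) + t_res + q/(1-q) m_short`, with `q` the merge
#' probability per exit and `m_short` the mean merged excursion.  The
#' estimator inverts this relation:
#' `1/k = (1-q)(mean_obs - t_res) - q m_short`.
#'
#' `q` is estimated by direct counting rather than by extrapolating a
#' parametric fit: the same paths are also segmented at a minimal
#' two-frame resolution, where the excursions that the dwell-extraction
#' resolution merges are individually visible; only the small mass of
#' excursions below two frames is extrapolated, with an exponential rate
#' fitted to the short-excursion window by truncated moment matching.
#' With no observable excursions the estimator reduces to the plain
#' inverse mean.
#'
#' @param paths list of [viterbi()] results.
#' @param state 1-based state index whose exit rate is estimated
#'   (e.g. the scrunched state for unscrunching rates).
#' @param n_states number of model states (validation).
#' @param resolution_frames imposed resolution (frames, default 5).
#' @param min_n minimum usable dwells.
#' @return List with `rate` (corrected, s^-1), `rate_raw` (plain inverse
#'   mean), `se`, `n`, `q`, `return_prob`, `mean_dwell_obs` and
#'   `resolution_s`.
#' @export
dwell_rate_corrected <- function(paths, state, n_states = NULL,
                                 resolution_frames = 5, min_n = 10) {
  dt <- paths[[1]]$frame_interval
  t_res <- resolution_frames * dt
  fpaths <- lapply(paths, impose_resolution, resolution_frames)
  ds <- extract_dwells(fpaths, state, n_states = n_states)
  dwells <- ds$dwells
  if (length(dwells) < min_n)
    stop("only ", length(dwells), " usable dwells (need >= ", min_n, ")",
         call. = FALSE)
  mean_obs <- mean(dwells)

  res_small <- min(2L, resolution_frames)
  fine <- collect_excursions(lapply(paths, impose_resolution, res_small),
                             state, dt)
  n_exits <- fine$n_ret + fine$n_noret
  if (length(fine$exc) >= 5 && n_exits > 0 && resolution_frames > res_small) {
    a <- res_small * dt
    short <- fine$exc[fine$exc < t_res]          # visible merged excursions
    # extrapolate the invisible sub-`a` mass from the short-excursion window
    b <- max(3 * t_res, 1)
    win <- fine$exc[fine$exc >= a & fine$exc <= b]
    if (length(win) >= 10) {
      k_f <- truncated_exp_rate(win, a, b)
      n_ab <- length(win)
      hidden <- n_ab * (1 - exp(-k_f * a)) /
        max(exp(-k_f * a) - exp(-k_f * b), 1e-12)
      m_sub <- 1 / k_f - a * exp(-k_f * a) / (1 - exp(-k_f * a))
    } else {
      hidden <- 0; m_sub <- a / 2
    }
    q <- min((hidden + length(short)) / (n_exits + hidden), 0.6)
    m_short <- if (hidden + length(short) > 0)
      (hidden * m_sub + sum(short)) / (hidden + length(short)) else 0
    r_hat <- fine$n_ret / n_exits
  } else {
    r_hat <- if (n_exits > 0) fine$n_ret / n_exits else NA_real_
    q <- 0; m_short <- 0
  }
  mean_corr <- max((1 - q) * (mean_obs - t_res) - q * m_short, dt)
  k <- 1 / mean_corr
  list(rate = k, rate_raw = 1 / mean_obs, se = k / sqrt(length(dwells)),
       n = length(dwells), q = q, return_prob = r_hat,
       mean_dwell_obs = mean_obs, resolution_s = t_res,
       censored_first = ds$censored_first, censored_last = ds$censored_last)
}

#' Synchronized FRET evolution map
#'
#' Overlays traces synchronized at the first raw frame whose FRET
#' efficiency reaches `threshold` (time zero), building an occupancy
#' matrix over FRET bins versus time offset.  Each column is normalized by
#' the number of traces contributing at that offset; traces that never
#' cross are excluded and counted.
#'
#' @param fret_traces list of [fret_trace()] objects.
#' @param threshold synchronization level (default 0.5).
#' @param window `c(before, after)` time window around time zero (s).
#' @param bins,range FRET binning.
#' @return An object of class `evolution_map`: `counts` (FRET bins x time
#'   offsets), `density` (column-normalized), `n_contrib` per column,
#'   `time_offsets` (s), `bin_edges`, `n_traces`, `n_excluded`.
#' @export
evolution_map <- function(fret_traces, threshold = 0.5,
                          window = c(-10, 30), bins = 30,
                          range = c(-0.1, 1.1)) {
  dt <- fret_traces[[1]]$frame_interval
  f0 <- ceiling(window[1] / dt); f1 <- floor(window[2] / dt)
  offsets <- f0:f1
  edges <- seq(range[1], range[2], length.out = bins + 1)
  counts <- matrix(0L, bins, length(offsets))
  n_contrib <- integer(length(offsets))
  n_excluded <- 0L
  for (ft in fret_traces) {
    y <- fret_values(ft)
    cross <- which(y >= threshold)[1]
    if (is.na(cross)) { n_excluded <- n_excluded + 1L; next }
    for (ci in seq_along(offsets)) {
      f <- cross + offsets[ci]
      if (f < 1 || f > length(y)) next
      b <- findInterval(y[f], edges)
      if (b >= 1 && b <= bins) {
        counts[b, ci] <- counts[b, ci] + 1L
        n_contrib[ci] <- n_contrib[ci] + 1L
      }
    }
  }
  dens <- sweep(counts, 2, pmax(n_contrib, 1L), "/")
  structure(list(counts = counts, density = dens, n_contrib = n_contrib,
                 time_offsets = offsets * dt, bin_edges = edges,
                 threshold = threshold,
                 n_traces = length(fret_traces) - n_excluded,
                 n_excluded = n_excluded),
            class = "evolution_map")
}

#' Population time course from per-minute histograms
#'
#' Refits only the component weights of a frozen mixture template (means
#' and widths from the equilibrium fit) to each per-minute histogram by
#' non-negative weighted least squares, yielding per-state population
#' fractions with propagated errors.  Time points where the refit
#' degenerates are flagged, never fabricated.
#'
#' @param hists list of [build_histogram()] results, one per time bin.
#' @param template a [fit_mixture()] result providing frozen means/sds.
#' @param times numeric time of each histogram (min); defaults to
#'   `0, 1, ...`.
#' @return An object of class `population_timecourse`: data.frame `table`
#'   with `time`, one `fraction_*`/`se_*` pair per component, and
#'   `flagged`.
#' @export
washout_timecourse <- function(hists, template, times = NULL) {
  stop_if_not(inherits(template, "mixture_fit"), "template must be a mixture_fit")
  m <- template$components$mean
  s <- template$components$sd
  k <- length(m)
  times <- times %||% (seq_along(hists) - 1)
  rows <- lapply(seq_along(hists), function(i) {
    h <- hists[[i]]
    x <- hist_centers(h)
    bw <- diff(h$bin_edges[1:2])
    X <- vapply(seq_len(k), function(j) bw * dnorm(x, m[j], s[j]),
                numeric(length(x)))
    w <- 1 / pmax(h$counts, 1)
    sw <- sqrt(w)
    ans <- tryCatch(pracma::lsqnonneg(sw * X, sw * h$counts),
                    error = function(e) NULL)
    if (is.null(ans) || sum(ans$x) <= 0)
      return(c(time = times[i], rep(NA_real_, 2 * k), flagged = 1))
    a <- ans$x
    XtWX <- t(X) %*% (w * X)
    dof <- max(sum(h$counts > 0) - k, 1)
    sigma2 <- sum(w * (h$counts - X %*% a)^2) / dof
    va <- tryCatch(sigma2 * solve(XtWX), error = function(e)
      matrix(NA_real_, k, k))
    tot <- sum(a)
    frac <- a / tot
    fr_se <- vapply(seq_len(k), function(j) {
      grad <- -a[j] / tot^2 * rep(1, k); grad[j] <- grad[j] + 1 / tot
      if (anyNA(va)) return(NA_real_)
      sqrt(max(drop(t(grad) %*% va %*% grad), 0))
    }, numeric(1))
    c(time = times[i], frac, fr_se, flagged = 0)
  })
  tab <- as.data.frame(do.call(rbind, rows))
  names(tab) <- c("time", paste0("fraction_", seq_len(k)),
                  paste0("se_", seq_len(k)), "flagged")
  structure(list(table = tab, component_means = m,
                 k = k),
            class = "population_timecourse")
}

#' Fit a single-exponential decay
#'
#' Least squares of `a + b exp(-k t)` with initialization from log-linear
#' regression of the tail-subtracted values.  Non-decaying series return a
#' rate near zero with a large standard error and are flagged.
#'
#' @param time,value the series (>= 4 points); `value` may also be passed
#'   as a data.frame with columns `time` and `value` in the first
#'   argument.
#' @param offset fix the plateau at this value instead of fitting it
#'   (e.g. 0 for populations known to empty); `NULL` fits a free offset.
#'   Fixing the plateau greatly stabilizes fits that span only a few
#'   half-lives.
#' @return An object of class `decay_fit`: `amplitude`, `rate` (same
#'   inverse time unit as `time`), `offset`, `half_life = ln 2 / rate`,
#'   standard errors, `r_squared` and a `flagged` indicator.
#' @export
fit_decay <- function(time, value = NULL, offset = NULL) {
  if (is.data.frame(time)) { value <- time$value; time <- time$time }
  stop_if_not(length(time) >= 4, "need at least 4 points")
  n <- length(time)
  off0 <- offset %||% mean(tail(value, max(3, round(n / 10))))
  amp0 <- value[1] - off0
  pos <- (value - off0) / ifelse(amp0 >= 0, 1, -1)
  usable <- pos > max(abs(amp0) * 0.05, 1e-12)
  k0 <- if (sum(usable) >= 3) {
    sl <- coef(lm(log(pos[usable]) ~ time[usable]))[2]
    max(-sl, 1e-8)
  } else 1 / max(diff(range(time)), 1)
  fit <- tryCatch({
    if (is.null(offset))
      minpack.lm::nlsLM(value ~ a + b * exp(-k * time),
                        start = list(a = off0, b = amp0, k = k0),
                        lower = c(-Inf, -Inf, 0),
                        control = minpack.lm::nls.lm.control(maxiter = 500))
    else
      minpack.lm::nlsLM(value ~ offset + b * exp(-k * time),
                        start = list(b = amp0, k = k0),
                        lower = c(-Inf, 0),
                        control = minpack.lm::nls.lm.control(maxiter = 500))
  }, error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(amplitude = amp0, rate = 0, offset = off0,
                          half_life = Inf, amplitude_se = NA_real_,
                          rate_se = NA_real_, offset_se = NA_real_,
                          half_life_se = NA_real_, r_squared = 0,
                          flagged = TRUE),
                     class = "decay_fit"))
  }
  p <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e)
    setNames(rep(NA_real_, length(coef(fit))), names(coef(fit))))
  if (is.null(offset)) off_fit <- unname(p["a"]) else off_fit <- offset
  resid <- value - predict(fit)
  r2 <- 1 - sum(resid^2) / sum((value - mean(value))^2)
  k <- unname(p["k"])
  hl <- log(2) / k
  structure(list(amplitude = unname(p["b"]), rate = k,
                 offset = off_fit,
                 half_life = hl,
                 amplitude_se = unname(se["b"]), rate_se = unname(se["k"]),
                 offset_se = if (is.null(offset)) unname(se["a"]) else 0,
                 half_life_se = unname(log(2) * se["k"] / k^2),
                 r_squared = r2,
                 flagged = !is.finite(k) || k <= 0 ||
                   (is.finite(se["k"]) && k < 2 * se["k"])),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat("Single-exponential decay: rate =", signif(x$rate, 4),
      "+/-", signif(x$rate_se, 2),
      "| half-life =", signif(x$half_life, 4),
      "| R^2 =", signif(x$r_squared, 4),
      if (x$flagged) "[flagged: non-decaying]" else "", "\n")
  invisible(x)
}

filter_short_runs <- function(h, min_frames) {
  if (min_frames <= 1 || length(h) == 0) return(h)
  r <- rle(h)
  # merge runs shorter than the resolution limit into the preceding run
  for (i in seq_along(r$lengths)) {
    if (i > 1 && r$lengths[i] < min_frames)
      r$values[i] <- r$values[i - 1]
  }
  inverse.rle(r)
}

#' Classify post-washout trajectories by branching outcome
#'
#' Each trace recorded after NTP washout, starting in the high-FRET
#' (scrunched) state, is classified as: `transient` when the high state is
#' left and later re-entered before the trace ends; `irreversible` when it
#' is left and never re-entered; `no_drop` otherwise.  Excursions shorter
#' than `min_frames` frames are treated as noise flicker and merged away.
#'
#' @param fret_traces list of [fret_trace()] objects recorded after the
#'   washout marker.
#' @param high_threshold FRET level separating the high state from the
#'   rest (e.g. midway between the open and scrunched means).
#' @param min_frames minimum run length for a genuine state visit
#'   (default 3).
#' @return List with `fractions` (named, transient / irreversible /
#'   no_drop), binomial `se`, `counts`, `n` and `n_rejected` (traces not
#'   starting in the high state).
#' @export
classify_post_washout <- function(fret_traces, high_threshold,
                                  min_frames = 3) {
  classes <- character(0)
  n_rejected <- 0L
  for (ft in fret_traces) {
    y <- fret_values(ft)
    if (length(y) < min_frames) { n_rejected <- n_rejected + 1L; next }
    h <- filter_short_runs(y >= high_threshold, min_frames)
    if (!h[1]) { n_rejected <- n_rejected + 1L; next }
    r <- rle(h)
    if (length(r$values) == 1) cls <- "no_drop"
    else if (any(r$values[-1])) cls <- "transient"
    else cls <- "irreversible"
    classes <- c(classes, cls)
  }
  n <- length(classes)
  stop_if_not(n > 0, "no classifiable traces (all rejected)")
  lv <- c("transient", "irreversible", "no_drop")
  counts <- vapply(lv, function(l) sum(classes == l), integer(1))
  p <- counts / n
  list(fractions = p, se = sqrt(p * (1 - p) / n), counts = counts,
       n = n, n_rejected = n_rejected)
}
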