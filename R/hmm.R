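trace_obs <- function(fret_traces) {
  lapply(fret_traces, fret_values)
}

#' Fit a pooled Gaussian-emission hidden Markov model
#'
#' Maximum-likelihood Baum-Welch across all traces with shared emission
#' parameters and a shared per-frame transition matrix: the estimand used
#' to quantify promoter opening/closing and scrunching/unscrunching
#' dynamics.  EM runs to convergence (relative log-likelihood change below
#' `tol` or `max_iter` iterations) from `n_restarts` seeded starts: a
#' Gaussian decomposition of the pooled FRET histogram, k-means centres,
#' an even grid over the pooled range, then jittered quantile grids
#' (the mixed strategy is robust to very uneven state occupancies).
#' Each restart runs a capped number of iterations and only the best is
#' pursued to full convergence (the usual short-runs/long-run EM
#' economy); the whole fit is deterministic given `seed`.  Restarts in
#' which a state is starved of occupancy (fewer than one expected frame)
#' are discarded.
#'
#' @param fret_traces list of [fret_trace()] objects (masked frames are
#'   excluded before fitting).
#' @param n_states number of hidden states (default 3).
#' @param seed integer seed.
#' @param n_restarts seeded restarts (>= 5 recommended).
#' @param max_iter EM iteration cap.
#' @param tol relative log-likelihood convergence tolerance.
#' @param frame_interval frame length (s), taken from the first trace when
#'   `NULL`.
#' @return An object of class `hmm_model`: `means`, `sds` (ascending
#'   means), `transition_matrix` (per-frame probabilities, rows summing to
#'   one), `initial_probs`, `log_likelihood`, `ll_trace` (per-iteration
#'   log-likelihoods of the winning restart), `expected_transitions`, and
#'   bookkeeping fields.
#' @export
fit_hmm <- function(fret_traces, n_states = 3, seed = 1, n_restarts = 5,
                    max_iter = 300, tol = 1e-6, frame_interval = NULL) {
  ys <- trace_obs(fret_traces)
  ys <- ys[vapply(ys, length, 1L) > 0]
  total <- sum(vapply(ys, length, 1L))
  stop_if_not(total >= 50, "need at least 50 unmasked frames in total")
  frame_interval <- frame_interval %||% fret_traces[[1]]$frame_interval
  K <- n_states
  pool <- unlist(ys)
  seed_stream(seed)

  run_em <- function(means0, sds0, A0, pi0, iter_cap, ll_trace0 = numeric(0)) {
    means <- means0; sds <- sds0; A <- A0; pi <- pi0
    ll_trace <- ll_trace0
    ll_prev <- -Inf
    stats <- NULL
    for (it in seq_len(iter_cap)) {
      stats <- hmm_estep_cpp(ys, means, sds, A, pi)
      ll <- stats$loglik
      ll_trace <- c(ll_trace, ll)
      if (any(stats$occ < 1)) return(list(starved = TRUE))
      # M-step (pooled sufficient statistics)
      pi <- stats$init / sum(stats$init)
      rs <- rowSums(stats$trans)
      A <- stats$trans / ifelse(rs > 0, rs, 1)
      A[rs == 0, ] <- diag(K)[rs == 0, ]
      means <- stats$m1 / stats$occ
      sds <- sqrt(pmax(stats$m2 / stats$occ - means^2, 1e-6))
      if (is.finite(ll_prev) && abs(ll - ll_prev) < tol * abs(ll_prev)) break
      ll_prev <- ll
    }
    list(starved = FALSE, means = means, sds = sds, A = A, pi = pi,
         loglik = ll_trace[length(ll_trace)], ll_trace = ll_trace,
         trans = stats$trans, n_iter = length(ll_trace))
  }

  mix_centers <- if (K > 1) tryCatch({
    h <- build_histogram(pool)
    sort(fit_mixture(h, min(K, 3), seed = 1)$components$mean)
  }, error = function(e) NULL) else NULL
  km_centers <- tryCatch({
    km <- stats::kmeans(pool, centers = K, nstart = 5, iter.max = 50)
    sort(as.numeric(km$centers))
  }, error = function(e) NULL)
  rng <- as.numeric(quantile(pool, c(0.005, 0.995)))

  best <- NULL; n_starved <- 0
  for (r in seq_len(n_restarts)) {
    if (r == 1 && length(mix_centers) == K) {
      means0 <- mix_centers               # histogram decomposition
    } else if (r == 2 && !is.null(km_centers)) {
      means0 <- km_centers
    } else if (r == 3) {
      means0 <- seq(rng[1], rng[2], length.out = K + 2)[seq_len(K) + 1]
    } else {
      probs <- (seq_len(K) - 0.5) / K
      probs <- pmin(pmax(probs + runif(K, -0.2, 0.2), 0.02), 0.98)
      means0 <- sort(as.numeric(quantile(pool, probs)))
    }
    sds0 <- rep(max(sd(pool) / max(K, 2), 0.02), K)
    A0 <- matrix(0.05 / max(K - 1, 1), K, K); diag(A0) <- 0.95
    if (K == 1) A0 <- matrix(1, 1, 1)
    pi0 <- rep(1 / K, K)
    # short run: full convergence is only pursued for the best restart
    res <- run_em(means0, sds0, A0, pi0, iter_cap = min(40, max_iter))
    if (res$starved) { n_starved <- n_starved + 1; next }
    if (is.null(best) || res$loglik > best$loglik) best <- res
  }
  if (is.null(best))
    stop("all ", n_restarts, " restarts left a state starved of occupancy; ",
         "try fewer states", call. = FALSE)
  if (best$n_iter >= min(40, max_iter)) {
    cont <- run_em(best$means, best$sds, best$A, best$pi,
                   iter_cap = max_iter - best$n_iter,
                   ll_trace0 = best$ll_trace)
    if (!isTRUE(cont$starved)) best <- cont
  }

  ord <- order(best$means)
  structure(list(n_states = K,
                 means = best$means[ord], sds = best$sds[ord],
                 transition_matrix = best$A[ord, ord, drop = FALSE],
                 initial_probs = best$pi[ord],
                 log_likelihood = best$loglik,
                 ll_trace = best$ll_trace,
                 expected_transitions = best$trans[ord, ord, drop = FALSE],
                 n_traces_used = length(ys),
                 n_frames_used = total,
                 frame_interval = frame_interval,
                 n_iter = best$n_iter,
                 n_starved_restarts = n_starved),
            class = "hmm_model")
}

#' @export
print.hmm_model <- function(x, ...) {
  cat("Gaussian HMM,", x$n_states, "states |", x$n_traces_used, "traces,",
      x$n_frames_used, "frames | logLik", signif(x$log_likelihood, 8), "\n")
  cat("means:", signif(x$means, 4), "\nsds:  ", signif(x$sds, 4), "\n")
  cat("per-frame transition matrix:\n")
  print(signif(x$transition_matrix, 4))
  invisible(x)
}

#' Viterbi decoding of a FRET trace
#'
#' Most-likely state path under a fitted model; ties break toward the
#' lower state index.  Decoding runs over the unmasked frames.
#'
#' @param model an [fit_hmm()] result.
#' @param trace a [fret_trace()].
#' @return An object of class `state_path`: per-frame `states` and a
#'   `segments` data.frame (state, start_frame, end_frame) tiling the
#'   decoded region with no same-state adjacency.
#' @export
viterbi <- function(model, trace) {
  y <- fret_values(trace)
  if (length(y) == 0) {
    return(structure(list(trace_id = trace$trace_id, states = integer(0),
                          segments = data.frame(state = integer(0),
                                                start_frame = integer(0),
                                                end_frame = integer(0)),
                          frame_interval = model$frame_interval),
                     class = "state_path"))
  }
  s <- hmm_viterbi_cpp(y, model$means, model$sds,
                       model$transition_matrix, model$initial_probs)
  r <- rle(s)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  structure(list(trace_id = trace$trace_id, states = s,
                 segments = data.frame(state = r$values,
                                       start_frame = starts,
                                       end_frame = ends),
                 frame_interval = model$frame_interval),
            class = "state_path")
}

#' Transition density plot from decoded paths
#'
#' One count per decoded transition at (mean observed FRET of the
#' departing segment, mean observed FRET of the arriving segment), binned
#' as in [build_histogram()].
#'
#' @param paths list of [viterbi()] results.
#' @param fret_traces the corresponding [fret_trace()] objects (matched by
#'   `trace_id`).
#' @param bins,range binning as in [build_histogram()].
#' @param condition provenance label.
#' @return An object of class `transition_density`: `matrix` over (FRET
#'   before, FRET after) bins, `n_transitions`, `bin_edges`, `condition`.
#' @export
transition_density <- function(paths, fret_traces, bins = 60,
                               range = c(-0.1, 1.1), condition = NULL) {
  edges <- seq(range[1], range[2], length.out = bins + 1)
  M <- matrix(0L, bins, bins)
  byid <- setNames(fret_traces,
                   vapply(fret_traces, function(f) f$trace_id, ""))
  n_tr <- 0L
  for (p in paths) {
    ft <- byid[[p$trace_id]]
    if (is.null(ft)) next
    y <- fret_values(ft)
    seg <- p$segments
    if (nrow(seg) < 2) next
    segmean <- vapply(seq_len(nrow(seg)), function(i)
      mean(y[seg$start_frame[i]:seg$end_frame[i]]), numeric(1))
    for (i in seq_len(nrow(seg) - 1)) {
      bi <- findInterval(segmean[i], edges)
      bj <- findInterval(segmean[i + 1], edges)
      if (bi >= 1 && bi <= bins && bj >= 1 && bj <= bins) {
        M[bi, bj] <- M[bi, bj] + 1L
        n_tr <- n_tr + 1L
      }
    }
  }
  structure(list(matrix = M, n_transitions = n_tr, bin_edges = edges,
                 condition = condition),
            class = "transition_density")
}

#' Transition rates implied by a fitted HMM
#'
#' First-order rates `k_ij = p_ij / dt` for every off-diagonal transition
#' probability, plus (for 2-state models) the exact embedded-chain
#' correction `k_ij = p_ij * (-log lambda) / ((1 - lambda) dt)` with
#' `lambda = 1 - p_12 - p_21` the second eigenvalue of the transition
#' matrix.  Standard errors follow from the expected transition counts of
#' the EM fit (binomial error on each row).
#'
#' @param model an [fit_hmm()] result.
#' @return data.frame with `from`, `to`, `rate` (s^-1, first order),
#'   `rate_exact` (2-state only, else `NA`), and `se`.  Zero transition
#'   probabilities give zero rates with a one-sided error bound.
#' @export
rates_from_model <- function(model) {
  A <- model$transition_matrix
  dt <- model$frame_interval
  K <- model$n_states
  n_from <- rowSums(model$expected_transitions)
  out <- NULL
  lambda <- if (K == 2) 1 - A[1, 2] - A[2, 1] else NA_real_
  for (i in seq_len(K)) for (j in seq_len(K)) {
    if (i == j) next
    p <- A[i, j]
    se_p <- if (n_from[i] > 0) sqrt(max(p * (1 - p), p) / n_from[i]) else NA_real_
    exact <- if (K == 2 && is.finite(lambda) && lambda > 0 && lambda < 1)
      p * (-log(lambda)) / ((1 - lambda) * dt) else NA_real_
    out <- rbind(out, data.frame(from = i, to = j, rate = p / dt,
                                 rate_exact = exact, se = se_p / dt))
  }
  out
}
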