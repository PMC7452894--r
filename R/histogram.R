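#' Build a FRET efficiency histogram
#'
#' Deterministic binning of block-averaged FRET values into half-open bins
#' `[lo, hi)`; values outside the range are dropped and counted.
#'
#' @param block_values numeric FRET values (typically from
#'   [block_average()]).
#' @param bins number of bins (default 60).
#' @param range histogram range (default `c(-0.1, 1.1)`).
#' @param condition provenance label (e.g. `"IC7"`).
#' @param n_traces number of traces contributing, for the record.
#' @return An object of class `fret_histogram` with `bin_edges`, `counts`,
#'   `n_values`, `n_dropped`, `n_traces`, `condition`.
#' @export
build_histogram <- function(block_values, bins = 60, range = c(-0.1, 1.1),
                            condition = NULL, n_traces = NA_integer_) {
  stop_if_not(all(is.finite(block_values)), "values must be finite")
  edges <- seq(range[1], range[2], length.out = bins + 1)
  idx <- findInterval(block_values, edges)       # [edges[i], edges[i+1])
  inside <- idx >= 1 & idx <= bins
  counts <- tabulate(idx[inside], nbins = bins)
  if (length(block_values) == 0)
    warning("empty input; zero-count histogram")
  structure(list(bin_edges = edges, counts = counts,
                 n_values = sum(counts),
                 n_dropped = sum(!inside),
                 n_traces = n_traces, condition = condition),
            class = "fret_histogram")
}

hist_centers <- function(hist) {
  e <- hist$bin_edges
  (e[-1] + e[-length(e)]) / 2
}

#' @export
print.fret_histogram <- function(x, ...) {
  cat("FRET histogram", if (!is.null(x$condition)) paste0("(", x$condition, ")"),
      "-", length(x$counts), "bins,", x$n_values, "values\n")
  invisible(x)
}

mixture_curve <- function(x, area, mean, sd, binwidth) {
  out <- numeric(length(x))
  for (j in seq_along(area))
    out <- out + area[j] * binwidth * dnorm(x, mean[j], sd[j])
  out
}

#' Fit a 1-3 component Gaussian mixture to a FRET histogram
#'
#' Weighted least squares of a sum of `k` Gaussian peaks to the bin
#' counts, with Poisson weights (`1/max(count, 1)`), seeded multi-start
#' over a grid of candidate means, and parameter standard errors from the
#' covariance at the optimum.  Starts in which a component collapses below
#' the bin width are discarded.  The fit is deterministic given `seed`.
#'
#' @param hist a [build_histogram()] result.
#' @param k number of components (1, 2 or 3).
#' @param n_starts number of seeded starts (>= 10 recommended).
#' @param seed integer seed for the start grid.
#' @return An object of class `mixture_fit`: a `components` data.frame
#'   (weight, mean, sd and their standard errors, means ascending),
#'   reduced chi-square, Poisson log-likelihood and BIC.
#' @export
fit_mixture <- function(hist, k, n_starts = 10, seed = 1) {
  stop_if_not(k %in% 1:3, "k must be 1, 2 or 3")
  x <- hist_centers(hist)
  y <- hist$counts
  occupied <- sum(y > 0)
  stop_if_not(occupied >= 3 * k + 2,
              paste0("too few occupied bins (", occupied,
                     ") to fit k = ", k, " components"))
  bw <- diff(hist$bin_edges[1:2])
  w <- 1 / pmax(y, 1)
  n_tot <- sum(y)

  seed_stream(seed)
  # weighted quantiles of the empirical distribution as mean candidates
  cum <- cumsum(y) / n_tot
  wq <- function(p) x[which.max(cum >= p)]
  occ_range <- range(x[y > 0])
  starts <- list()
  for (r in seq_len(n_starts)) {
    if (r %% 2 == 0) {
      # even spacing over the occupied range finds rare, well-separated peaks
      m0 <- seq(occ_range[1], occ_range[2], length.out = k + 2)[2:(k + 1)] +
        runif(k, -bw, bw)
    } else {
      probs <- (seq_len(k) - 0.5) / k
      if (r > 1) probs <- pmin(pmax(probs + runif(k, -0.25, 0.25), 0.02), 0.98)
      m0 <- sort(vapply(probs, wq, numeric(1))) + runif(k, -bw, bw)
    }
    s0 <- rep(max(0.05, bw * 2), k) * runif(k, 0.8, 1.5)
    a0 <- rep(n_tot / k, k)
    starts[[r]] <- list(a = a0, m = m0, s = s0)
  }

  best <- NULL
  for (st in starts) {
    fit <- tryCatch({
      p0 <- c(st$a, st$m, st$s)
      names(p0) <- c(paste0("a", 1:k), paste0("m", 1:k), paste0("s", 1:k))
      fn <- function(p) {
        mixture_curve(x, p[1:k], p[k + 1:k], p[2 * k + 1:k], bw)
      }
      minpack.lm::nls.lm(
        par = p0,
        fn = function(p) sqrt(w) * (y - fn(p)),
        lower = c(rep(0, k), rep(min(x), k), rep(bw / 2, k)),
        upper = c(rep(10 * n_tot, k), rep(max(x), k), rep(diff(range(x)), k)),
        control = minpack.lm::nls.lm.control(maxiter = 200))
    }, error = function(e) NULL)
    if (is.null(fit)) next
    p <- coef(fit)
    sds <- p[2 * k + 1:k]
    if (any(sds < bw)) next                 # collapsed component
    if (any(p[1:k] <= 1e-9 * n_tot) && k > 1) {
      # vanished component: keep but flag via weight ~ 0; still comparable
    }
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss)
      best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    stop("mixture fit failed to converge for condition ",
         hist$condition %||% "(unlabelled)", call. = FALSE)

  fit <- best$fit
  p <- coef(fit)
  a <- p[1:k]; m <- p[k + 1:k]; s <- p[2 * k + 1:k]
  ord <- order(m)
  a <- a[ord]; m <- m[ord]; s <- s[ord]

  covm <- tryCatch({
    dof <- occupied - 3 * k
    vc <- vcov(fit)
    vc[c(ord, k + ord, 2 * k + ord), c(ord, k + ord, 2 * k + ord)]
  }, error = function(e) matrix(NA_real_, 3 * k, 3 * k))
  se <- sqrt(pmax(diag(covm), 0))
  a_se <- se[1:k]; m_se <- se[k + 1:k]; s_se <- se[2 * k + 1:k]

  tot <- sum(a)
  wgt <- a / tot
  # delta-method error of normalized weights
  wgt_se <- vapply(seq_len(k), function(j) {
    grad <- -a[j] / tot^2 * rep(1, k)
    grad[j] <- grad[j] + 1 / tot
    va <- covm[1:k, 1:k, drop = FALSE]
    if (anyNA(va)) return(NA_real_)
    sqrt(max(drop(t(grad) %*% va %*% grad), 0))
  }, numeric(1))

  mu_fit <- mixture_curve(x, a, m, s, bw)
  dof <- max(occupied - 3 * k, 1)
  chisq_red <- sum(w * (y - mu_fit)^2) / dof
  mu_pos <- pmax(mu_fit, 1e-8)
  loglik <- sum(y * log(mu_pos) - mu_pos - lgamma(y + 1))
  bic <- -2 * loglik + 3 * k * log(length(y))

  structure(list(
    k = k,
    components = data.frame(weight = wgt, mean = m, sd = s,
                            weight_se = wgt_se, mean_se = m_se, sd_se = s_se),
    areas = a, area_se = a_se,
    chisq_red = chisq_red, loglik = loglik, bic = bic,
    n_values = hist$n_values, condition = hist$condition,
    converged = fit$info %in% 1:4),
    class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("Gaussian mixture fit, k =", x$k, "| reduced chi-sq =",
      signif(x$chisq_red, 3), "| BIC =", signif(x$bic, 6), "\n")
  print(x$components, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Select the number of Gaussian components by BIC
#'
#' Fits `k = 1..3` and picks the minimal Bayesian information criterion;
#' ties favour the smaller k (parsimony).  Small samples
#' (`n_values < min_n`) fall back to k = 1 with a low-power warning.
#'
#' @param hist a [build_histogram()] result.
#' @param min_n minimum sample size for model selection (default 200).
#' @param seed passed to [fit_mixture()].
#' @return List with `best_k`, `fit` (the selected [fit_mixture()]),
#'   and `criteria` (BIC per k; `NA` where the fit failed).
#' @export
select_k <- function(hist, min_n = 200, seed = 1) {
  if (hist$n_values < min_n) {
    warning("only ", hist$n_values,
            " values; selection underpowered, falling back to k = 1")
    fit <- fit_mixture(hist, 1, seed = seed)
    return(list(best_k = 1L, fit = fit,
                criteria = c(`1` = fit$bic, `2` = NA, `3` = NA)))
  }
  fits <- lapply(1:3, function(k)
    tryCatch(fit_mixture(hist, k, seed = seed), error = function(e) NULL))
  bic <- vapply(fits, function(f) if (is.null(f)) NA_real_ else f$bic,
                numeric(1))
  stop_if_not(any(is.finite(bic)), "all mixture fits failed")
  best <- which(bic == min(bic, na.rm = TRUE))[1]   # ties -> smaller k
  list(best_k = as.integer(best), fit = fits[[best]],
       criteria = setNames(bic, 1:3))
}

#' Per-component population fractions with propagated errors
#'
#' Fractions are the component areas over the total area; errors come from
#' the weight covariances of the fit.  Fractions sum to one exactly.
#'
#' @param fit a [fit_mixture()] result.
#' @return data.frame with `component`, `mean`, `fraction`, `se`.
#' @export
population_fractions <- function(fit) {
  stop_if_not(inherits(fit, "mixture_fit"), "fit must be a mixture_fit")
  data.frame(component = seq_len(fit$k),
             mean = fit$components$mean,
             fraction = fit$components$weight,
             se = if (fit$k == 1) 0 else fit$components$weight_se)
}
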