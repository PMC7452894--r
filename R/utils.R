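#' @useDynLib scrunchFRET, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats dnorm density median quantile rexp rnorm rpois runif
#'   sd optim setNames coef vcov rbinom var pexp lm predict
#' @importFrom utils head tail write.table read.table modifyList
#'   packageVersion
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 0

#' Set the package random stream
#'
#' All stochastic operations accept a single integer seed and draw every
#' random number from R's default Mersenne-Twister stream seeded once.
#' @param seed integer seed, or `NULL` to leave the stream untouched.
#' @keywords internal
seed_stream <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}
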