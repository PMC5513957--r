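# Trial-level reaction-time generator: slope model plus shifted-lognormal noise.

# Linear-scale rescaling factor s such that SD(s * (L - E[L])) = sdR for
# log(L) ~ N(0, sigma_log^2). Var(L) = exp(2 sigma^2) - exp(sigma^2).
lognorm_scale <- function(sdR, sigma_log) {
  sdR / sqrt(exp(2 * sigma_log^2) - exp(sigma_log^2))
}

#' Lower bound of the shifted-lognormal error distribution
#'
#' The trial error is `e = s * (L - E[L])` with `L` lognormal, so it is
#' bounded below by `-s * E[L]` (approached as `L -> 0`).
#'
#' @param sdR linear-scale error SD in ms.
#' @param sigma_log log-scale SD of the lognormal.
#' @return The finite lower bound of the error distribution (ms, negative).
#' @export
error_lower_bound <- function(sdR, sigma_log = 0.5) {
  -lognorm_scale(sdR, sigma_log) * exp(sigma_log^2 / 2)
}

#' Draw intra-individual RT errors
#'
#' Errors are i.i.d. shifted, rescaled lognormal draws:
#' `e = s * (L - E[L])` with `log(L) ~ N(0, sigma_log^2)` and `s` chosen so
#' that `SD(e) = sdR` exactly. Hence `E[e] = 0`, `SD(e) = sdR`, the
#' distribution is right-skewed and bounded below by [error_lower_bound()].
#'
#' @param count number of draws, >= 1.
#' @param sdR linear-scale error SD in ms, > 0.
#' @param sigma_log log-scale SD of the lognormal ("logarithmic
#'   compression"), > 0; default 0.5.
#' @return Numeric vector of `count` error values in ms.
#' @examples
#' e <- sample_error(1e4, sdR = 75)
#' c(mean(e), sd(e))  # approx 0 and 75
#' @export
sample_error <- function(count, sdR, sigma_log = 0.5) {
  if (!is.numeric(count) || length(count) != 1L || count < 1 ||
      count != round(count))
    stop("`count` must be a single integer >= 1", call. = FALSE)
  if (!is.numeric(sdR) || length(sdR) != 1L || !is.finite(sdR) || sdR <= 0)
    stop("`sdR` must be a single positive number", call. = FALSE)
  if (!is.numeric(sigma_log) || length(sigma_log) != 1L ||
      !is.finite(sigma_log) || sigma_log <= 0)
    stop("`sigma_log` must be a single positive number", call. = FALSE)
  s <- lognorm_scale(sdR, sigma_log)
  s * (exp(sigma_log * stats::rnorm(count)) - exp(sigma_log^2 / 2))
}

#' Simulate one subject's trials
#'
#' Generates the complete `2 * |magnitudes| * k` reaction times of one
#' simulated subject under the slope model: for magnitude `m`,
#' `RT_right = intercept + m*slope/2 + e` and
#' `RT_left = intercept - m*slope/2 + e'`, with independent errors per
#' trial drawn by [sample_error()].
#'
#' @param params a one-group [sim_params()] object.
#' @param errors optional numeric vector of length `2 * |magnitudes| * k`
#'   (or a scalar, recycled) replacing the random errors; a deterministic
#'   hook used for exact checks.
#' @return A `subject_trials` object: an array `rt[k, magnitude, hand]`
#'   with hands `"right"` and `"left"`, carrying the magnitude set as an
#'   attribute.
#' @examples
#' p <- sim_params(slope = -4, n = 10, k = 2, sdR = 75)
#' tr <- simulate_subject(p, errors = 0)
#' tr[1, "9", "right"]  # 500 + 9*(-4)/2 = 482
#' @export
simulate_subject <- function(params, errors = NULL) {
  stopifnot(inherits(params, "sim_params"))
  if (params$two_group)
    stop("`simulate_subject()` needs a one-group `sim_params` (single slope)",
         call. = FALSE)
  m <- params$magnitudes
  M <- length(m)
  k <- params$k
  ntr <- 2L * M * k
  if (is.null(errors)) {
    e <- sample_error(ntr, params$sdR, params$sigma_log)
  } else {
    if (!length(errors) %in% c(1L, ntr))
      stop("`errors` must have length 1 or 2 * |magnitudes| * k",
           call. = FALSE)
    e <- rep_len(as.numeric(errors), ntr)
  }
  half <- rep(m * params$slope / 2, each = k)
  rt <- array(c(params$intercept + half + e[seq_len(M * k)],
                params$intercept - half + e[M * k + seq_len(M * k)]),
              dim = c(k, M, 2L),
              dimnames = list(NULL, as.character(m), c("right", "left")))
  structure(rt, magnitudes = m, class = c("subject_trials", "array"))
}

#' Simulate an independent sample of subjects
#'
#' All subjects share the same true slope; there is no between-subject
#' slope variance in the generative model.
#'
#' @param params a one-group [sim_params()] object.
#' @param n number of subjects; defaults to `params$n`.
#' @return A list of `n` `subject_trials` objects.
#' @export
simulate_sample <- function(params, n = params$n) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop("`n` must be a single positive integer", call. = FALSE)
  lapply(seq_len(n), function(i) simulate_subject(params))
}
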