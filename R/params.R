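#' Simulation parameters for one experimental cell
#'
#' Bundles the generative settings of a single simulated SNARC experiment:
#' the true SNARC slope (or the two group slopes for a two-group design),
#' the number of subjects, repetitions per magnitude per hand, the
#' intra-individual reaction-time standard deviation, the lognormal noise
#' shape, the stimulus magnitude set, and a common baseline RT.
#'
#' The reaction-time model is
#' \deqn{RT_{right}(m) = intercept + m \cdot slope/2 + e, \quad
#'       RT_{left}(m)  = intercept - m \cdot slope/2 + e',}
#' with independent shifted-lognormal errors per trial (mean 0, SD `sdR`),
#' so that the expected right-minus-left difference at magnitude \eqn{m}
#' is \eqn{m \cdot slope}. The intercept is identical for both hands and
#' cancels exactly in the dRT difference.
#'
#' @param slope true SNARC slope in ms per magnitude unit (negative =
#'   canonical SNARC). Supply either `slope` (one-group) or both `slope_a`
#'   and `slope_b` (two-group).
#' @param n subjects per sample (per group in two-group designs), >= 2.
#' @param k repetitions per magnitude per hand, >= 1.
#' @param sdR intra-individual RT standard deviation in ms, > 0.
#' @param sigma_log log-scale SD ("logarithmic compression") of the
#'   lognormal noise; default 0.5.
#' @param magnitudes ordered integer stimulus magnitudes; default `0:9`.
#' @param intercept baseline RT in ms, common to both hands; default 500.
#' @param slope_a,slope_b group slopes for a two-group design (ms per unit).
#'
#' @return An object of class `sim_params`.
#' @examples
#' sim_params(slope = -5, n = 20, k = 20, sdR = 75)
#' sim_params(slope_a = -2, slope_b = 2, n = 20, k = 20, sdR = 75)
#' @export
sim_params <- function(slope = NULL, n, k, sdR, sigma_log = 0.5,
                       magnitudes = 0:9, intercept = 500,
                       slope_a = NULL, slope_b = NULL) {
  two_group <- !is.null(slope_a) || !is.null(slope_b)
  if (two_group) {
    if (is.null(slope_a) || is.null(slope_b))
      stop("two-group parameters need both `slope_a` and `slope_b`",
           call. = FALSE)
    if (!is.null(slope))
      stop("supply either `slope` or `slope_a`/`slope_b`, not both",
           call. = FALSE)
    stopifnot(is.numeric(slope_a), length(slope_a) == 1L, is.finite(slope_a),
              is.numeric(slope_b), length(slope_b) == 1L, is.finite(slope_b))
  } else {
    if (is.null(slope))
      stop("`slope` is required for a one-group design", call. = FALSE)
    stopifnot(is.numeric(slope), length(slope) == 1L, is.finite(slope))
  }
  if (!is.numeric(n) || length(n) != 1L || n < 2 || n != round(n))
    stop("`n` must be a single integer >= 2", call. = FALSE)
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k))
    stop("`k` must be a single integer >= 1", call. = FALSE)
  if (!is.numeric(sdR) || length(sdR) != 1L || !is.finite(sdR) || sdR <= 0)
    stop("`sdR` must be a single positive number (ms)", call. = FALSE)
  if (!is.numeric(sigma_log) || length(sigma_log) != 1L ||
      !is.finite(sigma_log) || sigma_log <= 0)
    stop("`sigma_log` must be a single positive number", call. = FALSE)
  magnitudes <- as.numeric(magnitudes)
  if (length(magnitudes) < 3L || anyDuplicated(magnitudes) ||
      is.unsorted(magnitudes))
    stop("`magnitudes` must be >= 3 distinct ordered values", call. = FALSE)
  stopifnot(is.numeric(intercept), length(intercept) == 1L,
            is.finite(intercept))

  structure(
    list(slope = slope, slope_a = slope_a, slope_b = slope_b,
         sld = if (two_group) slope_b - slope_a else NULL,
         n = as.integer(n), k = as.integer(k), sdR = sdR,
         sigma_log = sigma_log, magnitudes = magnitudes,
         intercept = intercept, two_group = two_group),
    class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  if (x$two_group) {
    cat(sprintf("SNARC simulation parameters (two-group): slope_a = %g, slope_b = %g (sld = %g)\n",
                x$slope_a, x$slope_b, x$sld))
  } else {
    cat(sprintf("SNARC simulation parameters (one-group): slope = %g ms/unit\n",
                x$slope))
  }
  cat(sprintf("  n = %d subjects, k = %d repetitions, sdR = %g ms, sigma_log = %g\n",
              x$n, x$k, x$sdR, x$sigma_log))
  cat(sprintf("  magnitudes: %s; intercept = %g ms\n",
              paste(x$magnitudes, collapse = " "), x$intercept))
  invisible(x)
}
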