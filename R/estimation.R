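# dRT slope method: per-magnitude RT differences, per-subject OLS slopes.

#' dRT profile of one subject
#'
#' For each magnitude, averages the `k` right-hand RTs and the `k`
#' left-hand RTs and takes the right-minus-left difference. Negative dRT
#' values indicate faster right-hand responses.
#'
#' @param trials a `subject_trials` object from [simulate_subject()].
#' @return Named numeric vector of dRT values (ms), one per magnitude.
#' @export
drt_profile <- function(trials) {
  if (!inherits(trials, "subject_trials"))
    stop("`trials` must be a `subject_trials` object", call. = FALSE)
  if (anyNA(trials) || any(!is.finite(trials)))
    stop("incomplete subject data: non-finite RTs", call. = FALSE)
  colMeans(trials[, , "right", drop = FALSE][, , 1L]) -
    colMeans(trials[, , "left", drop = FALSE][, , 1L])
}

#' Ordinary least-squares SNARC slope
#'
#' Regresses a dRT profile on number magnitude and returns the slope,
#' `sum((m - mbar) * (drt - drtbar)) / sum((m - mbar)^2)`. For magnitudes
#' 0--9 the denominator is 82.5.
#'
#' @param drt numeric vector of dRT values (ms), one per magnitude.
#' @param magnitudes the magnitudes the profile is aligned with; defaults
#'   to the names of `drt`, else `0:9`.
#' @return The slope in ms per magnitude unit.
#' @examples
#' ols_slope(-(0:9), 0:9)  # exactly -1
#' @export
ols_slope <- function(drt, magnitudes = NULL) {
  if (is.null(magnitudes)) {
    magnitudes <- if (!is.null(names(drt))) as.numeric(names(drt)) else 0:9
  }
  magnitudes <- as.numeric(magnitudes)
  drt <- as.numeric(drt)
  if (length(drt) != length(magnitudes))
    stop("`drt` and `magnitudes` must have equal length", call. = FALSE)
  if (length(drt) < 3L)
    stop("degenerate regression: fewer than 3 magnitude points",
         call. = FALSE)
  if (anyNA(drt) || any(!is.finite(drt)))
    stop("non-finite dRT values", call. = FALSE)
  mc <- magnitudes - mean(magnitudes)
  sxx <- sum(mc^2)
  if (sxx == 0)
    stop("degenerate regression: zero magnitude variance", call. = FALSE)
  sum(mc * (drt - mean(drt))) / sxx
}

#' Per-subject SNARC slopes for one simulated sample
#'
#' Applies [drt_profile()] and [ols_slope()] to every subject and collects
#' the slopes with their sample mean and SD (n - 1 denominator).
#'
#' @param sample list of `subject_trials` (see [simulate_sample()]), or a
#'   plain numeric vector of already-estimated slopes.
#' @param magnitudes magnitude set; defaults to the set stored in the
#'   trials.
#' @return A `slope_set` object: list with `slopes`, `mean_slope`,
#'   `sd_slope`, `n`.
#' @export
sample_slopes <- function(sample, magnitudes = NULL) {
  if (is.numeric(sample)) return(slope_set(sample))
  if (!is.list(sample) || length(sample) == 0L)
    stop("`sample` must be a non-empty list of subject trials",
         call. = FALSE)
  slopes <- vapply(sample, function(tr) {
    mags <- if (is.null(magnitudes)) attr(tr, "magnitudes") else magnitudes
    ols_slope(drt_profile(tr), mags)
  }, numeric(1))
  slope_set(slopes)
}

#' Construct a slope set
#'
#' @param slopes numeric vector of per-subject SNARC slopes (ms per unit),
#'   length >= 2 (the one-sample test downstream needs an SD).
#' @return A `slope_set` object.
#' @export
slope_set <- function(slopes) {
  slopes <- as.numeric(slopes)
  if (length(slopes) < 2L)
    stop("a slope set needs at least 2 subjects (SD is undefined for n = 1)",
         call. = FALSE)
  if (anyNA(slopes) || any(!is.finite(slopes)))
    stop("non-finite slopes", call. = FALSE)
  structure(list(slopes = slopes, mean_slope = mean(slopes),
                 sd_slope = stats::sd(slopes), n = length(slopes)),
            class = "slope_set")
}

#' @export
print.slope_set <- function(x, ...) {
  cat(sprintf("SNARC slope set: n = %d, mean = %.3f ms/unit, sd = %.3f\n",
              x$n, x$mean_slope, x$sd_slope))
  invisible(x)
}
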