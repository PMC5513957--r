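# Significance machinery for slope sets: one-sample test against zero,
# two-sample test of a group difference, binary significance coding.

default_alphas <- c(0.05, 0.01, 0.001)

# element-wise label ("0.05", not the width-padded vector format "0.050")
alpha_label <- function(a) vapply(a, format, character(1))

new_snarc_test <- function(t, df, p, alphas, method) {
  sig <- code_significance(p, alphas)
  names(sig) <- alpha_label(alphas)
  structure(list(t_statistic = t, degrees_of_freedom = df, p_value = p,
                 sig = sig, method = method),
            class = "snarc_test")
}

#' One-sample SNARC test
#'
#' Tests the mean per-subject slope against zero with a one-sided
#' one-sample t-test in the canonical SNARC direction (alternative:
#' mean slope < 0): `t = mean / (sd / sqrt(n))`, `df = n - 1`,
#' `p = P(T_df <= t)`.
#'
#' @param slopes a [slope_set()] (or numeric vector of slopes, n >= 2).
#' @param alphas significance levels to code; default 0.05, 0.01, 0.001.
#' @return A `snarc_test` object with `t_statistic`, `degrees_of_freedom`,
#'   `p_value` and a 0/1 `sig` vector per alpha.
#' @export
one_sample_snarc_test <- function(slopes, alphas = default_alphas) {
  if (is.numeric(slopes)) slopes <- slope_set(slopes)
  stopifnot(inherits(slopes, "slope_set"))
  check_alphas(alphas)
  if (slopes$sd_slope <= 0)
    stop("degenerate slope variance: all slopes equal", call. = FALSE)
  tval <- slopes$mean_slope / (slopes$sd_slope / sqrt(slopes$n))
  df <- slopes$n - 1L
  p <- stats::pt(tval, df)
  new_snarc_test(tval, df, p, alphas, "one-sample t (one-sided, slope < 0)")
}

#' Two-sample slope-difference test
#'
#' Compares the mean slopes of two independent groups with Student's
#' pooled-variance independent-samples t-test (two-sided),
#' `df = n_a + n_b - 2`.
#'
#' @param slopes_a,slopes_b [slope_set()] objects (or numeric vectors) for
#'   the two groups.
#' @param alphas significance levels to code.
#' @return A `snarc_test` object.
#' @export
two_sample_slope_test <- function(slopes_a, slopes_b,
                                  alphas = default_alphas) {
  if (is.numeric(slopes_a)) slopes_a <- slope_set(slopes_a)
  if (is.numeric(slopes_b)) slopes_b <- slope_set(slopes_b)
  stopifnot(inherits(slopes_a, "slope_set"), inherits(slopes_b, "slope_set"))
  check_alphas(alphas)
  na <- slopes_a$n; nb <- slopes_b$n
  sp2 <- ((na - 1) * slopes_a$sd_slope^2 + (nb - 1) * slopes_b$sd_slope^2) /
    (na + nb - 2)
  if (sp2 <= 0)
    stop("degenerate slope variance in both groups", call. = FALSE)
  tval <- (slopes_a$mean_slope - slopes_b$mean_slope) /
    sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2L
  p <- 2 * stats::pt(-abs(tval), df)
  new_snarc_test(tval, df, p, alphas, "two-sample pooled t (two-sided)")
}

#' Code a p-value as significant or not
#'
#' Returns 1 iff `p < alpha` (strict inequality). Vectorized over `alpha`.
#'
#' @param p p-value(s) in \[0, 1\].
#' @param alpha significance level(s) in (0, 1).
#' @return Integer 0/1, one per alpha (or per p if alpha is scalar).
#' @export
code_significance <- function(p, alpha) {
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop("`p` must lie in [0, 1]", call. = FALSE)
  check_alphas(alpha)
  as.integer(outer(p, alpha, `<`))
}

check_alphas <- function(alphas) {
  if (!is.numeric(alphas) || length(alphas) == 0L ||
      any(alphas <= 0) || any(alphas >= 1))
    stop("alpha levels must lie in (0, 1)", call. = FALSE)
  invisible(alphas)
}

#' @export
print.snarc_test <- function(x, ...) {
  cat(sprintf("%s\n  t = %.4f, df = %d, p = %.4g\n  significant at: %s\n",
              x$method, x$t_statistic, x$degrees_of_freedom, x$p_value,
              paste(sprintf("%s -> %d", names(x$sig), x$sig),
                    collapse = ", ")))
  invisible(x)
}
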