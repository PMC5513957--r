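# Between-cells factorial ANOVA on binary significance outcomes.
#
# The design is balanced by construction (equal replications per cell), so
# sums of squares are computed exactly from the cell-mean decomposition
# (orthogonal: Type I/II/III coincide) rather than through a generic
# regression fit -- exact and fast at hundreds of thousands of rows.

#' Balanced factorial ANOVA on simulation outcomes
#'
#' Decomposes a long outcome table (one row per simulated experiment, with
#' factor columns and a 0/1 response) into all main effects and
#' interactions up to the full order, with F-tests against the residual
#' mean square and partial eta squared per effect. The linear ANOVA is
#' applied to the binary responses as-is; see the package vignette for the
#' heteroscedasticity caveat.
#'
#' @param data data.frame, e.g. the `outcomes` table of [run_grid()].
#' @param response name of the 0/1 (or numeric) response column; default
#'   `"sig_05"`, the alpha = 0.05 coding.
#' @param factors character vector of factor column names; the row order
#'   of the returned table follows this order (main effects, then 2-way,
#'   3-way, ... interactions, then residuals).
#' @return An `anova_power_table` data.frame with columns `effect`, `df`,
#'   `SS`, `MS`, `F`, `p_value`, `partial_eta2`, `label`.
#' @export
factorial_anova <- function(data, response = "sig_05",
                            factors = c("k", "slope_or_sld", "sdR", "n")) {
  stopifnot(is.data.frame(data))
  missing_cols <- setdiff(c(response, factors), names(data))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  y <- as.numeric(data[[response]])
  if (anyNA(y)) stop("response contains NA", call. = FALSE)
  f <- lapply(data[factors], factor)
  counts <- table(f)
  if (any(counts == 0) || length(unique(as.vector(counts))) != 1L)
    stop("unbalanced design: unequal replications per cell", call. = FALSE)
  r <- as.vector(counts)[1]
  if (r < 2) stop("need >= 2 replications per cell", call. = FALSE)

  dims <- vapply(f, nlevels, integer(1))
  nf <- length(dims)
  cellmean <- tapply(y, f, mean)
  grand <- mean(y)
  ss_total <- sum((y - grand)^2)

  subsets <- unlist(lapply(seq_len(nf), function(sz) {
    cmb <- utils::combn(nf, sz)
    lapply(seq_len(ncol(cmb)), function(j) cmb[, j])
  }), recursive = FALSE)
  key <- function(s) paste(s, collapse = ",")

  effects <- list()
  rows <- vector("list", length(subsets))
  for (idx in seq_along(subsets)) {
    S <- subsets[[idx]]
    mS <- apply(cellmean, S, mean)
    eff <- mS - grand
    for (T in subsets[lengths(subsets) < length(S)]) {
      if (all(T %in% S))
        eff <- eff - expand_effect(effects[[key(T)]], match(T, S), dims[S])
    }
    effects[[key(S)]] <- eff
    rows[[idx]] <- data.frame(
      effect = paste(factors[S], collapse = ":"),
      df = prod(dims[S] - 1L),
      SS = r * prod(dims[-S]) * sum(eff^2))
  }
  tab <- do.call(rbind, rows)
  ss_res <- max(ss_total - sum(tab$SS), 0)
  df_res <- length(y) - prod(dims)
  tab$MS <- tab$SS / tab$df
  ms_res <- ss_res / df_res
  tab$F <- tab$MS / ms_res
  tab$p_value <- stats::pf(tab$F, tab$df, df_res, lower.tail = FALSE)
  # constant response: every SS is 0 and eta is undefined
  tab$partial_eta2 <- ifelse(tab$SS == 0 & ss_res == 0, NA_real_,
                             tab$SS / (tab$SS + ss_res))
  tab$label <- NA_character_
  ok <- !is.na(tab$partial_eta2)
  tab$label[ok] <- effect_size_label(tab$partial_eta2[ok])
  tab <- rbind(tab, data.frame(effect = "Residuals", df = df_res,
                               SS = ss_res, MS = ms_res, F = NA,
                               p_value = NA, partial_eta2 = NA, label = NA))
  rownames(tab) <- NULL
  class(tab) <- c("anova_power_table", "data.frame")
  tab
}

# Broadcast an effect array defined on dims[pos] to the full `dims` shape.
expand_effect <- function(eff, pos, dims) {
  others <- setdiff(seq_along(dims), pos)
  arr <- array(eff, dim = c(dims[pos], dims[others]))
  aperm(arr, match(seq_along(dims), c(pos, others)))
}

#' Partial eta squared
#'
#' `SS_effect / (SS_effect + SS_residual)`.
#'
#' @param ss_effect,ss_residual sums of squares, both >= 0, not both 0.
#' @return Value in \[0, 1\].
#' @examples
#' partial_eta_sq(16707, 25525)  # 0.3956
#' @export
partial_eta_sq <- function(ss_effect, ss_residual) {
  if (!is.numeric(ss_effect) || !is.numeric(ss_residual) ||
      ss_effect < 0 || ss_residual < 0)
    stop("sums of squares must be non-negative", call. = FALSE)
  if (ss_effect == 0 && ss_residual == 0)
    stop("partial eta squared undefined: both sums of squares are zero",
         call. = FALSE)
  ss_effect / (ss_effect + ss_residual)
}

#' Effect-size label for partial eta squared
#'
#' Conventional bands: < 0.01 negligible; \[0.01, 0.06) small;
#' \[0.06, 0.14) moderate; >= 0.14 large.
#'
#' @param eta partial eta squared value(s) in \[0, 1\].
#' @return Character vector of labels.
#' @export
effect_size_label <- function(eta) {
  if (!is.numeric(eta) || anyNA(eta) || any(eta < 0) || any(eta > 1))
    stop("`eta` must lie in [0, 1]", call. = FALSE)
  c("negligible", "small", "moderate", "large")[
    findInterval(eta, c(0.01, 0.06, 0.14)) + 1L]
}

#' @export
print.anova_power_table <- function(x, digits = 4, ...) {
  cat("Factorial ANOVA on simulation outcomes\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}
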