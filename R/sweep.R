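# Replicated simulated experiments over factorial grids; per-cell power.
#
# The per-cell runners use a vectorized path that consumes the RNG stream
# in exactly the same order as the subject-by-subject generator in model.R
# (each subject draws 2 * |magnitudes| * k errors in one block), so a cell
# run is reproducible against the naive per-subject pipeline.

#' Factorial grid specification
#'
#' Describes a full factorial power sweep: the factor levels (slope sizes
#' for a one-group sweep or slope differences for a two-group sweep,
#' sample sizes, repetitions per item, intra-individual SDs), the number
#' of replications per cell, the alpha levels, and the master seed from
#' which per-cell substream seeds are derived.
#'
#' @param mode `"one_group"` (power to detect a SNARC effect) or
#'   `"two_group"` (power to detect a slope difference between groups).
#' @param slopes one-group slope levels (ms/unit); required for
#'   `mode = "one_group"`.
#' @param slope_diffs between-group slope differences (ms/unit); required
#'   for `mode = "two_group"`. Each difference `sld` is realized
#'   symmetrically as slopes `base - sld/2` and `base + sld/2`.
#' @param n,k,sdR factor levels for sample size, repetitions per item and
#'   intra-individual SD.
#' @param replications replications per cell; default 1000.
#' @param alphas significance levels; default 0.05, 0.01, 0.001.
#' @param magnitudes stimulus magnitude set; default `0:9`.
#' @param sigma_log lognormal compression; default 0.5.
#' @param intercept baseline RT (ms); default 500.
#' @param slope_base centre of the symmetric two-group slope split;
#'   default 0 (the difference test is location-invariant).
#' @param seed master seed (integer).
#' @return A `power_grid_spec` object.
#' @examples
#' paper_grid <- power_grid_spec("one_group", slopes = c(-7, -5, -3, -1),
#'                               n = c(10, 20, 30, 40), k = c(10, 20, 30, 40),
#'                               sdR = c(75, 150, 225, 300), seed = 1)
#' nrow(enumerate_grid(paper_grid))  # 256
#' @export
power_grid_spec <- function(mode = c("one_group", "two_group"),
                            slopes = NULL, slope_diffs = NULL,
                            n, k, sdR, replications = 1000,
                            alphas = default_alphas, magnitudes = 0:9,
                            sigma_log = 0.5, intercept = 500,
                            slope_base = 0, seed = 1L) {
  mode <- match.arg(mode)
  eff <- if (mode == "one_group") slopes else slope_diffs
  if (is.null(eff) || length(eff) == 0L)
    stop(sprintf("`%s` must be a non-empty numeric vector for mode %s",
                 if (mode == "one_group") "slopes" else "slope_diffs", mode),
         call. = FALSE)
  if (length(n) == 0L || length(k) == 0L || length(sdR) == 0L)
    stop("all factor level lists must be non-empty", call. = FALSE)
  if (!is.numeric(replications) || length(replications) != 1L ||
      replications < 1)
    stop("`replications` must be >= 1", call. = FALSE)
  check_alphas(alphas)
  if (!is.numeric(seed) || length(seed) != 1L || seed != round(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  structure(
    list(mode = mode, slope_or_sld = as.numeric(eff), n = as.integer(n),
         k = as.integer(k), sdR = as.numeric(sdR),
         replications = as.integer(replications), alphas = alphas,
         magnitudes = as.numeric(magnitudes), sigma_log = sigma_log,
         intercept = intercept, slope_base = slope_base,
         seed = as.integer(seed)),
    class = "power_grid_spec")
}

#' Enumerate the cells of a factorial grid
#'
#' Cartesian product of the factor levels in a fixed, documented order:
#' slope (or slope difference) varies fastest, then `n`, then `k`, then
#' `sdR`.
#'
#' @param spec a [power_grid_spec()].
#' @return A data.frame with columns `cell`, `slope_or_sld`, `n`, `k`,
#'   `sdR`, one row per cell.
#' @export
enumerate_grid <- function(spec) {
  stopifnot(inherits(spec, "power_grid_spec"))
  g <- expand.grid(slope_or_sld = spec$slope_or_sld, n = spec$n, k = spec$k,
                   sdR = spec$sdR, KEEP.OUT.ATTRS = FALSE)
  cbind(cell = seq_len(nrow(g)), g)
}

#' Derive a per-cell substream seed
#'
#' Counter-based scheme: `((master * 48271 + cell * 69621) mod 2147483563) + 1`,
#' evaluated in double precision (exact below 2^53). Stable across
#' versions, so any cell can be re-run in isolation.
#'
#' @param master master seed (integer).
#' @param cell 1-based cell index.
#' @return An integer seed.
#' @export
derive_cell_seed <- function(master, cell) {
  as.integer((as.double(master) * 48271 + as.double(cell) * 69621) %%
               2147483563) + 1L
}

# Vectorized core: per-subject OLS slope estimates for `n_subjects`
# independent subjects with a common true slope. Consumes the RNG in
# subject-major order, 2*M*k draws per subject (right block then left,
# repetition index fastest within magnitude), identical to
# simulate_subject(). Chunked to bound peak memory.
simulate_slope_estimates <- function(slope, n_subjects, k, sdR, sigma_log,
                                     magnitudes, max_chunk_draws = 2^23) {
  M <- length(magnitudes)
  mc <- magnitudes - mean(magnitudes)
  w <- mc / sum(mc^2)
  per_subj <- 2L * M * k
  s <- lognorm_scale(sdR, sigma_log)
  mu_l <- exp(sigma_log^2 / 2)
  out <- numeric(n_subjects)
  chunk <- max(1L, min(n_subjects, floor(max_chunk_draws / per_subj)))
  done <- 0L
  while (done < n_subjects) {
    nb <- min(chunk, n_subjects - done)
    z <- stats::rnorm(nb * per_subj)
    e <- s * (exp(sigma_log * z) - mu_l)
    mns <- colMeans(matrix(e, nrow = k))       # hand x magnitude cell means
    mm <- matrix(mns, nrow = 2L * M)           # one column per subject
    drt_noise <- mm[seq_len(M), , drop = FALSE] -
      mm[M + seq_len(M), , drop = FALSE]
    out[done + seq_len(nb)] <- slope + colSums(drt_noise * w)
    done <- done + nb
  }
  out
}

new_cell_outcome <- function(mode, params, replications, alphas, seed, p) {
  sig <- outer(p, alphas, `<`)
  storage.mode(sig) <- "integer"
  colnames(sig) <- alpha_label(alphas)
  structure(list(mode = mode, params = params,
                 replications = replications, alphas = alphas, seed = seed,
                 p_values = p, sig = sig),
            class = "cell_outcome")
}

#' Run one one-group design cell
#'
#' Replicates a simulated one-group SNARC experiment: generate a sample of
#' `n` subjects, estimate per-subject slopes, run the one-sided one-sample
#' t-test against zero, and code significance at each alpha.
#'
#' @param params a one-group [sim_params()].
#' @param replications number of simulated experiments.
#' @param alphas significance levels.
#' @param seed integer seed for this cell's substream.
#' @return A `cell_outcome` object with the per-replication p-values and
#'   a 0/1 significance matrix (replications x alphas).
#' @export
run_cell_one_group <- function(params, replications = 1000,
                               alphas = default_alphas, seed = 1L) {
  stopifnot(inherits(params, "sim_params"), !params$two_group)
  check_alphas(alphas)
  set.seed(seed)
  n <- params$n
  est <- simulate_slope_estimates(params$slope, n * replications, params$k,
                                  params$sdR, params$sigma_log,
                                  params$magnitudes)
  mat <- matrix(est, nrow = n)
  m <- colMeans(mat)
  v <- (colSums(mat^2) - n * m^2) / (n - 1)
  if (any(v <= 0))
    stop("degenerate replication: zero slope variance", call. = FALSE)
  tval <- m / sqrt(v / n)
  p <- stats::pt(tval, n - 1)
  new_cell_outcome("one_group", params, replications, alphas, seed, p)
}

#' Run one two-group design cell
#'
#' Replicates a simulated two-group comparison: two independent samples of
#' `n` subjects each (group A then group B within every replication),
#' per-subject slopes, pooled-variance two-sided t-test on the group
#' difference.
#'
#' @param params a two-group [sim_params()] (with `slope_a`, `slope_b`).
#' @inheritParams run_cell_one_group
#' @return A `cell_outcome` object.
#' @export
run_cell_two_group <- function(params, replications = 1000,
                               alphas = default_alphas, seed = 1L) {
  stopifnot(inherits(params, "sim_params"), params$two_group)
  check_alphas(alphas)
  set.seed(seed)
  n <- params$n
  # The true slope enters each estimate additively, so draw the noise part
  # once with slope 0 and add the group slopes afterwards.
  eps <- simulate_slope_estimates(0, 2L * n * replications, params$k,
                                  params$sdR, params$sigma_log,
                                  params$magnitudes)
  dim(eps) <- c(n, 2L, replications)
  a <- eps[, 1L, ] + params$slope_a
  b <- eps[, 2L, ] + params$slope_b
  if (replications == 1L) { a <- matrix(a); b <- matrix(b) }
  ma <- colMeans(a); mb <- colMeans(b)
  ssa <- colSums(a^2) - n * ma^2
  ssb <- colSums(b^2) - n * mb^2
  sp2 <- (ssa + ssb) / (2 * n - 2)
  if (any(sp2 <= 0))
    stop("degenerate replication: zero pooled variance", call. = FALSE)
  tval <- (ma - mb) / sqrt(sp2 * 2 / n)
  p <- 2 * stats::pt(-abs(tval), 2 * n - 2)
  new_cell_outcome("two_group", params, replications, alphas, seed, p)
}

#' Power estimate for one cell
#'
#' @param outcome a `cell_outcome`.
#' @param alpha one of the alpha levels the cell was coded at.
#' @return Named vector `c(power, mc_se)`: the proportion of significant
#'   replications and its binomial Monte Carlo standard error
#'   `sqrt(power * (1 - power) / replications)`.
#' @export
power_estimate <- function(outcome, alpha = 0.05) {
  stopifnot(inherits(outcome, "cell_outcome"))
  col <- match(alpha_label(alpha), colnames(outcome$sig))
  if (is.na(col))
    stop("cell was not coded at alpha = ", alpha, call. = FALSE)
  p <- mean(outcome$sig[, col])
  c(power = p, mc_se = sqrt(p * (1 - p) / outcome$replications))
}

#' Run a full factorial power sweep
#'
#' Executes every cell of the grid with its derived substream seed (see
#' [derive_cell_seed()]); cells are independent, so re-running a single
#' cell in isolation reproduces its rows exactly.
#'
#' @param spec a [power_grid_spec()].
#' @param keep_outcomes if `TRUE` (default), also return the long
#'   per-replication outcome table used by [factorial_anova()].
#' @param verbose print per-cell progress.
#' @return A list with `power`: one row per (cell, alpha) with columns
#'   `mode, slope_or_sld, n, k, sdR, alpha, replications, power, mc_se`;
#'   and `outcomes` (if kept): one row per (cell, replication) with the
#'   factor levels and one 0/1 column per alpha (`sig_05`, `sig_01`, ...).
#' @export
run_grid <- function(spec, keep_outcomes = TRUE, verbose = FALSE) {
  stopifnot(inherits(spec, "power_grid_spec"))
  cells <- enumerate_grid(spec)
  nal <- length(spec$alphas)
  pw <- vector("list", nrow(cells))
  oc <- if (keep_outcomes) vector("list", nrow(cells)) else NULL
  sig_names <- paste0("sig_", sub("^0\\.", "", alpha_label(spec$alphas)))
  for (i in seq_len(nrow(cells))) {
    row <- cells[i, ]
    seed_i <- derive_cell_seed(spec$seed, row$cell)
    if (spec$mode == "one_group") {
      params <- sim_params(slope = row$slope_or_sld, n = row$n, k = row$k,
                           sdR = row$sdR, sigma_log = spec$sigma_log,
                           magnitudes = spec$magnitudes,
                           intercept = spec$intercept)
      out <- run_cell_one_group(params, spec$replications, spec$alphas,
                                seed_i)
    } else {
      params <- sim_params(slope_a = spec$slope_base - row$slope_or_sld / 2,
                           slope_b = spec$slope_base + row$slope_or_sld / 2,
                           n = row$n, k = row$k, sdR = row$sdR,
                           sigma_log = spec$sigma_log,
                           magnitudes = spec$magnitudes,
                           intercept = spec$intercept)
      out <- run_cell_two_group(params, spec$replications, spec$alphas,
                                seed_i)
    }
    pows <- colMeans(out$sig)
    pw[[i]] <- data.frame(
      mode = spec$mode, slope_or_sld = row$slope_or_sld, n = row$n,
      k = row$k, sdR = row$sdR, alpha = spec$alphas,
      replications = spec$replications, power = as.numeric(pows),
      mc_se = sqrt(pows * (1 - pows) / spec$replications),
      row.names = NULL)
    if (keep_outcomes) {
      df <- data.frame(
        mode = spec$mode, slope_or_sld = row$slope_or_sld, n = row$n,
        k = row$k, sdR = row$sdR, replication = seq_len(spec$replications))
      df[sig_names] <- lapply(seq_len(nal), function(j) out$sig[, j])
      oc[[i]] <- df
    }
    if (verbose)
      message(sprintf("cell %d/%d done (power at %.3g: %.3f)",
                      i, nrow(cells), spec$alphas[1], pows[1]))
  }
  res <- list(power = do.call(rbind, pw),
              outcomes = if (keep_outcomes) do.call(rbind, oc) else NULL,
              spec = spec)
  class(res) <- "power_grid_result"
  res
}

#' @export
print.power_grid_result <- function(x, ...) {
  cat(sprintf("Power sweep (%s): %d cells x %d replications, alphas %s, seed %d\n",
              x$spec$mode, nrow(x$power) / length(x$spec$alphas),
              x$spec$replications,
              paste(alpha_label(x$spec$alphas), collapse = "/"),
              x$spec$seed))
  invisible(x)
}
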