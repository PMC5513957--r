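# Independent closed-form oracles used across tests.
#
# Under the generative model, a per-subject OLS slope estimate is the true
# slope plus a weighted sum of hand-by-magnitude error means, so its SD is
# sqrt(2 * sdR^2 / (k * Sxx)) with Sxx = sum((m - mbar)^2). Power then
# follows the noncentral t distribution.

sxx_of <- function(magnitudes = 0:9) sum((magnitudes - mean(magnitudes))^2)

theory_slope_sd <- function(sdR, k, magnitudes = 0:9) {
  sqrt(2 * sdR^2 / (k * sxx_of(magnitudes)))
}

# one-sample, one-sided (alternative slope < 0), alpha on the lower tail
closed_form_power_one <- function(slope, n, k, sdR, alpha = 0.05,
                                  magnitudes = 0:9) {
  ncp <- slope / (theory_slope_sd(sdR, k, magnitudes) / sqrt(n))
  pt(qt(alpha, n - 1), n - 1, ncp)
}

# two-sample pooled t, two-sided, equal n per group
closed_form_power_two <- function(sld, n, k, sdR, alpha = 0.05,
                                  magnitudes = 0:9) {
  ncp <- sld / (theory_slope_sd(sdR, k, magnitudes) * sqrt(2 / n))
  crit <- qt(1 - alpha / 2, 2 * n - 2)
  pt(-crit, 2 * n - 2, ncp) + 1 - pt(crit, 2 * n - 2, ncp)
}

# the four-factor grids the power sweeps are reported on
sim1_grid_spec <- function(replications, seed) {
  power_grid_spec("one_group", slopes = c(-7, -5, -3, -1),
                  n = c(10, 20, 30, 40), k = c(10, 20, 30, 40),
                  sdR = c(75, 150, 225, 300),
                  replications = replications, seed = seed)
}

sim2_grid_spec <- function(replications, seed) {
  power_grid_spec("two_group", slope_diffs = c(2, 4, 6, 8),
                  n = c(10, 20, 30, 40), k = c(10, 20, 30, 40),
                  sdR = c(75, 150, 225, 300),
                  replications = replications, seed = seed)
}

main_eta <- function(anova_tab, effect) {
  anova_tab$partial_eta2[anova_tab$effect == effect]
}
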