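# Power-curve plots: panels by intra-individual SD and sample size,
# repetitions on the x axis, one curve per slope (or slope difference).

#' Plot power curves from a power table
#'
#' Lays out the power surface the way SNARC design charts are usually
#' read: large panels (rows) by intra-individual SD (`sdR`), small panels
#' (columns) by sample size `n`, repetitions per item `k` on the x axis,
#' one curve per slope or slope difference, with horizontal reference
#' lines at the conventional 0.80 and 0.95 power levels.
#'
#' @param power_table the `power` data.frame of [run_grid()] (or one read
#'   back with [read_power_table()]).
#' @param alpha which coded alpha level to plot; default 0.05.
#' @param ref_lines horizontal reference powers; default `c(0.80, 0.95)`.
#' @return A ggplot object.
#' @export
plot_power <- function(power_table, alpha = 0.05,
                       ref_lines = c(0.80, 0.95)) {
  stopifnot(is.data.frame(power_table))
  need <- c("slope_or_sld", "n", "k", "sdR", "alpha", "power")
  missing_cols <- setdiff(need, names(power_table))
  if (length(missing_cols))
    stop("power table lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df <- power_table[power_table$alpha == alpha, , drop = FALSE]
  if (nrow(df) == 0)
    stop("no rows at alpha = ", alpha, call. = FALSE)
  if (any(df$power < 0 | df$power > 1))
    stop("power values outside [0, 1]", call. = FALSE)

  want <- expand.grid(slope_or_sld = unique(df$slope_or_sld),
                      n = unique(df$n), k = unique(df$k),
                      sdR = unique(df$sdR), KEEP.OUT.ATTRS = FALSE)
  have <- paste(df$slope_or_sld, df$n, df$k, df$sdR)
  gaps <- want[!paste(want$slope_or_sld, want$n, want$k, want$sdR) %in% have, ]
  if (nrow(gaps) > 0)
    stop("power table does not cover the full panel grid; missing cells:\n",
         paste(utils::capture.output(print(utils::head(gaps, 20))),
               collapse = "\n"), call. = FALSE)

  df$effect <- factor(df$slope_or_sld)
  lab <- if (all(df$mode == "two_group")) "slope difference (ms)" else
    "SNARC slope (ms)"
  ggplot2::ggplot(df, ggplot2::aes(x = k, y = power, colour = effect,
                                   group = effect)) +
    ggplot2::geom_hline(yintercept = ref_lines, colour = "black",
                        linewidth = 0.3) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_grid(sdR ~ n, labeller = ggplot2::label_both) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "repetitions per item (k)",
                  y = sprintf("power at alpha = %s", alpha_label(alpha)),
                  colour = lab) +
    ggplot2::theme_bw()
}
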