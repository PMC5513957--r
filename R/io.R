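# CSV interchange for power tables, outcome tables and ANOVA tables,
# plus config-file reading for the command-line driver. Doubles are
# written at 15 significant digits, so a table reads back equal to within
# one unit in the last written digit.

#' Write / read a power table
#'
#' @param power_table the `power` data.frame of [run_grid()].
#' @param path CSV file path.
#' @return `read_power_table()` returns the table as a data.frame;
#'   `write_power_table()` returns `path` invisibly.
#' @export
write_power_table <- function(power_table, path) {
  stopifnot(is.data.frame(power_table))
  data.table::fwrite(power_table, path)
  invisible(path)
}

#' @rdname write_power_table
#' @export
read_power_table <- function(path) {
  as.data.frame(data.table::fread(path))
}

#' Write a long outcome table
#'
#' @param outcomes the `outcomes` data.frame of [run_grid()].
#' @param path CSV file path.
#' @export
write_outcomes <- function(outcomes, path) {
  stopifnot(is.data.frame(outcomes))
  data.table::fwrite(outcomes, path)
  invisible(path)
}

#' Write an ANOVA table
#'
#' @param anova_table an `anova_power_table` from [factorial_anova()].
#' @param path CSV file path.
#' @export
write_anova_table <- function(anova_table, path) {
  stopifnot(is.data.frame(anova_table))
  data.table::fwrite(as.data.frame(anova_table), path)
  invisible(path)
}

#' Read a run configuration file
#'
#' Key-value configuration (YAML or JSON by extension) holding grid
#' levels, replications, alphas, magnitudes and the master seed; keys
#' mirror the arguments of [power_grid_spec()].
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the `yaml` package is required to read YAML configs",
           call. = FALSE)
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("the `jsonlite` package is required to read JSON configs",
           call. = FALSE)
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    stop("unsupported config format (use .yaml or .json): ", path,
         call. = FALSE)
  }
}

#' Build a grid spec from a configuration list
#'
#' @param config a named list, e.g. from [read_run_config()].
#' @return A [power_grid_spec()].
#' @export
grid_spec_from_config <- function(config) {
  allowed <- names(formals(power_grid_spec))
  unknown <- setdiff(names(config), allowed)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(power_grid_spec, config)
}
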