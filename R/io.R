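# Result writers. CSV files use the RFC-4180 dialect with a header row and
# '.' decimals; numeric columns are written with 17 significant digits so a
# read-back reconstructs every double exactly.

format_full <- function(df) {
  for (nm in names(df)) {
    if (is.numeric(df[[nm]]) && !is.integer(df[[nm]])) {
      df[[nm]] <- sprintf("%.17g", df[[nm]])
    }
  }
  df
}

write_csv_full <- function(df, path) {
  utils::write.csv(format_full(df), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a dense trajectory to CSV
#'
#' Columns `t, w, r, n, env, pulse_index`, full float precision.
#'
#' @param result A [simulate_sequence()] result (or its trajectory).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(result, path) {
  traj <- if (inherits(result, "simulation_result")) result$trajectory
          else result
  names(traj)[names(traj) == "pulse"] <- "pulse_index"
  write_csv_full(traj, path)
}

#' Write a simulation result summary to JSON
#'
#' Records `n_min`, the attaining pulse, the per-pulse local minima, the
#' end-of-best-pulse composition, and echoes the model and schedule
#' parameters.
#'
#' @param result A [simulate_sequence()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_result_json <- function(result, path) {
  stopifnot(inherits(result, "simulation_result"))
  p <- result$params
  obj <- list(
    n_min = result$n_min,
    n_min_time = result$n_min_time,
    best_pulse_index = result$best_pulse_index,
    composition_end_best_pulse =
      if (is.finite(result$composition_end_best_pulse))
        result$composition_end_best_pulse else "Inf",
    local_minima = result$local_minima,
    parameters = list(
      lambda_w = p$lambda_w, cost_k = p$cost_k, delta = p$delta,
      mu_w = p$mu_w, mu_r = p$mu_r,
      tau = result$sequence$shape$tau,
      t_r = result$sequence$shape$t_r,
      skew_s = result$sequence$shape$skew_s,
      n_pulses = result$sequence$n_pulses
    )
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Write sweep cells to CSV
#'
#' @param cells Data frame from [run_sweep()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(cells, path) write_csv_full(cells, path)

#' Read sweep cells back from CSV
#'
#' Exact inverse of [write_sweep_csv()] (doubles round-trip bit-exactly).
#'
#' @param path CSV path.
#' @return Data frame of sweep cells.
#' @export
read_sweep_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("is_best_N" %in% names(df)) df$is_best_N <- as.logical(df$is_best_N)
  df
}

#' Write an optimal-skewness line to CSV
#'
#' Columns `t_r, s_opt_grid, s_opt_predicted, n_min`.
#'
#' @param line Data frame from [optimal_skewness_line()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_optimal_line_csv <- function(line, path) {
  out <- data.frame(t_r = line$t_r, s_opt_grid = line$s_opt,
                    s_opt_predicted = line$s_opt_predicted,
                    n_min = line$n_min)
  write_csv_full(out, path)
}
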