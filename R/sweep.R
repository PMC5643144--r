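#' Configuration-space grid for pulse sweeps
#'
#' The space scanned is `(t_r, s)` for each pulse count `N`: the total
#' high-stress duration, the skewness placing it within the pulse, and how
#' many identical pulses the fixed total treatment time is split into.
#' Defaults reproduce the reference landscape: `total_tau = 60`, `t_r`
#' from 1 to 60 in unit steps, `s` from -1 to 1 in steps of 0.05, and
#' sequences of up to four pulses.
#'
#' @param total_tau Total treatment duration.
#' @param t_r_values Increasing grid of high-stress durations in
#'   `(0, total_tau]` (0 is allowed and yields the pure low-stress run).
#' @param s_values Skewness grid in `[-1, 1]`.
#' @param N_values Pulse counts (positive integers).
#' @return An object of class `sweep_grid`.
#' @export
sweep_grid <- function(total_tau = 60,
                       t_r_values = 1:60,
                       s_values = seq(-1, 1, by = 0.05),
                       N_values = 1:4) {
  stopifnot(
    is.numeric(total_tau), total_tau > 0,
    length(t_r_values) > 0, all(t_r_values >= 0),
    all(t_r_values <= total_tau), !is.unsorted(t_r_values),
    length(s_values) > 0, all(s_values >= -1), all(s_values <= 1),
    length(N_values) > 0, all(N_values >= 1),
    all(N_values == as.integer(N_values))
  )
  structure(list(total_tau = total_tau,
                 t_r_values = as.numeric(t_r_values),
                 s_values = as.numeric(s_values),
                 N_values = as.integer(N_values)),
            class = "sweep_grid")
}

#' Sweep the pulse-configuration space
#'
#' Simulates every `(t_r, s, N)` cell of the grid from the free-
#' environment fixed point and records the global population minimum, the
#' pulse attaining it, and the composition ratio `r/w` at the end of that
#' pulse. Cells are independent and the run is fully deterministic: two
#' runs with the same grid and parameters produce identical results.
#'
#' @param grid A [sweep_grid()].
#' @param params [model_params()].
#' @param output_step Dense-output step passed to [simulate_sequence()].
#' @return Data frame with one row per cell and columns `t_r`, `s`, `N`,
#'   `n_min`, `best_pulse_index`, `r_over_w_end`, and `is_best_N`
#'   (whether this `N` wins the cell's `(t_r, s)` comparison, ties broken
#'   toward smaller `N`).
#' @export
run_sweep <- function(grid, params = model_params(), output_step = 0.01) {
  stopifnot(inherits(grid, "sweep_grid"))
  init <- fixed_point("free", params)

  cells <- expand.grid(N = grid$N_values, s = grid$s_values,
                       t_r = grid$t_r_values,
                       KEEP.OUT.ATTRS = FALSE)
  m <- nrow(cells)
  n_min <- numeric(m); best_pulse <- integer(m); comp <- numeric(m)
  for (i in seq_len(m)) {
    res <- tryCatch({
      seqc <- build_sequence(grid$total_tau, cells$t_r[i], cells$s[i],
                             cells$N[i])
      simulate_sequence(seqc, init, params, output_step)
    }, error = function(e) {
      stop(sprintf("sweep cell (t_r = %g, s = %g, N = %d) failed: %s",
                   cells$t_r[i], cells$s[i], cells$N[i],
                   conditionMessage(e)), call. = FALSE)
    })
    n_min[i] <- res$n_min
    best_pulse[i] <- res$best_pulse_index
    comp[i] <- res$composition_end_best_pulse
  }

  out <- data.frame(t_r = cells$t_r, s = cells$s, N = cells$N,
                    n_min = n_min, best_pulse_index = best_pulse,
                    r_over_w_end = comp)
  out <- out[order(out$t_r, out$s, out$N), , drop = FALSE]
  rownames(out) <- NULL

  # winning N per (t_r, s); order(n_min, N) breaks ties toward smaller N
  out$is_best_N <- FALSE
  key <- paste(out$t_r, out$s)
  winners <- vapply(split(seq_len(nrow(out)), key), function(idx) {
    idx[order(out$n_min[idx], out$N[idx])[1L]]
  }, integer(1))
  out$is_best_N[winners] <- TRUE
  out
}

#' Winning sequence per configuration cell
#'
#' Reduces sweep cells to one row per `(t_r, s)`: the pulse count `N`
#' achieving the lowest population minimum (ties toward smaller `N` —
#' shorter, simpler treatment preferred), together with that sequence's
#' `n_min`, attaining pulse index and end-of-best-pulse composition.
#' Flags mark the regions where the winning sequence attains its minimum
#' in its first or in its last pulse.
#'
#' @param cells Sweep data frame from [run_sweep()].
#' @return Data frame with columns `t_r`, `s`, `best_N`, `n_min`,
#'   `best_pulse_index`, `r_over_w_end`, `min_in_first_pulse`,
#'   `min_in_last_pulse`.
#' @export
best_sequence_map <- function(cells) {
  stopifnot(is.data.frame(cells),
            all(c("t_r", "s", "N", "n_min") %in% names(cells)))
  pick <- do.call(rbind, lapply(
    split(cells, list(cells$t_r, cells$s), drop = TRUE),
    function(d) d[order(d$n_min, d$N)[1L], , drop = FALSE]))
  out <- data.frame(t_r = pick$t_r, s = pick$s, best_N = pick$N,
                    n_min = pick$n_min,
                    best_pulse_index = pick$best_pulse_index,
                    r_over_w_end = pick$r_over_w_end)
  out$min_in_first_pulse <- out$best_pulse_index == 1L
  out$min_in_last_pulse <- out$best_pulse_index == out$best_N
  out <- out[order(out$t_r, out$s), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Optimal-skewness line for an N-pulse sequence
#'
#' For each `t_r`, the skewness minimizing `n_min` at fixed `N` (ties
#' broken toward larger `s`, i.e. the longer initial wait, consistent
#' with the onset-time mechanism), compared with the predicted line
#' `s_o = 2 N t_o / (tau - t_r) - 1` clipped to `[-1, 1]`, where `t_o` is
#' the optimal initial low-stress duration from [find_t_o()].
#'
#' @param cells Sweep data frame from [run_sweep()].
#' @param N Pulse count to extract.
#' @param total_tau Total treatment duration used in the sweep.
#' @param t_o Optimal onset time; computed via [find_t_o()] from `params`
#'   when not supplied.
#' @param params [model_params()], used only when `t_o` is missing.
#' @return Data frame with columns `t_r`, `s_opt`, `n_min`,
#'   `s_opt_predicted` (NA at `t_r = total_tau`, where the skewness is
#'   degenerate).
#' @export
optimal_skewness_line <- function(cells, N = 1L, total_tau = 60,
                                  t_o = NULL, params = model_params()) {
  stopifnot(is.data.frame(cells), N %in% cells$N)
  if (is.null(t_o)) t_o <- find_t_o(params)
  sub <- cells[cells$N == N, , drop = FALSE]
  out <- do.call(rbind, lapply(split(sub, sub$t_r), function(d) {
    i <- order(d$n_min, -d$s)[1L]  # ties -> larger s
    data.frame(t_r = d$t_r[1L], s_opt = d$s[i], n_min = d$n_min[i])
  }))
  pred <- 2 * N * t_o / (total_tau - out$t_r) - 1
  pred[out$t_r >= total_tau] <- NA_real_
  out$s_opt_predicted <- pmin(pmax(pred, -1), 1)
  out <- out[order(out$t_r), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Single-pulse sweep at constant drug load
#'
#' Scans `(t_r, s)` for single pulses holding `t_sum = tau + alpha * t_r`
#' fixed instead of the duration `tau`. Infeasible `t_r` values (where
#' `t_sum - alpha * t_r < t_r`) are skipped with a warning.
#'
#' @param spec A [constant_load_spec()].
#' @param t_r_values,s_values Grids as in [sweep_grid()].
#' @param params [model_params()].
#' @param output_step Dense-output step.
#' @return Data frame with columns `t_r`, `s`, `tau`, `n_min`,
#'   `r_over_w_end`.
#' @export
constant_load_sweep <- function(spec, t_r_values, s_values,
                                params = model_params(),
                                output_step = 0.01) {
  stopifnot(inherits(spec, "constant_load_spec"))
  feasible <- spec$t_sum - spec$alpha * t_r_values >= t_r_values
  if (any(!feasible)) {
    warning(sprintf(
      "skipping %d infeasible t_r value(s) under constant load (t_r > %g)",
      sum(!feasible), spec$t_sum / (1 + spec$alpha)))
  }
  t_r_values <- t_r_values[feasible]
  init <- fixed_point("free", params)
  cells <- expand.grid(s = s_values, t_r = t_r_values,
                       KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    seqc <- build_constant_load(spec, cells$t_r[i], cells$s[i])
    res <- simulate_sequence(seqc, init, params, output_step)
    data.frame(t_r = cells$t_r[i], s = cells$s[i],
               tau = seqc$shape$tau, n_min = res$n_min,
               r_over_w_end = res$composition_end_best_pulse)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$t_r, out$s), , drop = FALSE]
  rownames(out) <- NULL
  out
}
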