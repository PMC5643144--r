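# ---- low-level integration -------------------------------------------------

# default solver tolerances; chosen so the t_o ~ 15 landmark is stable to
# +-0.01 under further tightening
.RTOL <- 1e-9
.ATOL <- 1e-12

# integrate one constant-environment segment from `state` over [0, duration],
# sampled at output_step plus the exact endpoint; returns matrix [t, w, r]
integrate_segment <- function(state, env, duration, params,
                              output_step = 0.01,
                              rtol = .RTOL, atol = .ATOL) {
  env <- match_env(env)
  stopifnot(duration > 0, output_step > 0)
  flags <- env_growth_flags(env)
  pvec <- c(params$lambda_w, params$lambda_r, params$delta,
            params$mu_w, params$mu_r, flags[["w"]], flags[["r"]])
  times <- seq(0, duration, by = output_step)
  if (times[length(times)] < duration) times <- c(times, duration)
  out <- deSolve::lsoda(
    y = as_state(state), times = times,
    func = "pd_derivs", parms = pvec,
    dllname = "pulsedyn", initfunc = "pd_initmod",
    rtol = rtol, atol = atol
  )
  if (nrow(out) < length(times) || any(!is.finite(out))) {
    stop(sprintf("integration failed in a '%s' segment of duration %g",
                 env, duration), call. = FALSE)
  }
  y <- unclass(out)[, 2:3, drop = FALSE]
  if (any(y < -10 * atol)) {
    stop(sprintf("state went negative beyond tolerance in a '%s' segment",
                 env), call. = FALSE)
  }
  y[y < 0] <- 0
  cbind(t = out[, 1], w = y[, 1], r = y[, 2])
}

# refine an interior minimum of n(t) bracketed by samples [i-1, i+1] of a
# segment: re-integrate the bracket on a fine grid, twice (each pass shrinks
# the time uncertainty by ~1/100, far below the 1e-3 contract)
refine_interior_min <- function(seg_mat, i, env, params, rtol, atol,
                                passes = 2L) {
  lo <- i - 1L
  t0 <- unname(seg_mat[lo, "t"])
  state <- seg_mat[lo, c("w", "r")]
  width <- unname(seg_mat[i + 1L, "t"]) - t0
  best <- c(t = unname(seg_mat[i, "t"]),
            n = unname(seg_mat[i, "w"] + seg_mat[i, "r"]))
  for (pass in seq_len(passes)) {
    fine <- integrate_segment(state, env, width, params,
                              output_step = width / 200, rtol = rtol,
                              atol = atol)
    n <- fine[, "w"] + fine[, "r"]
    j <- which.min(n)
    best <- c(t = t0 + unname(fine[j, "t"]), n = unname(n[j]))
    if (j <= 1L || j >= nrow(fine)) break
    # new bracket around the fine minimum
    t0 <- t0 + unname(fine[j - 1L, "t"])
    state <- fine[j - 1L, c("w", "r")]
    width <- unname(fine[j + 1L, "t"] - fine[j - 1L, "t"])
  }
  best
}

# ---- trajectory simulation -------------------------------------------------

#' Simulate the population through a pulse schedule
#'
#' Integrates the two-species dynamics segment by segment (the right-hand
#' side is smooth within a segment and discontinuous only at boundaries,
#' so the solver is restarted at every boundary and boundary times appear
#' exactly in the output). Within each pulse the lowest total population
#' is located, with interior minima refined by re-integration on nested
#' fine grids; the global minimum over the schedule, the 1-based index of
#' the pulse attaining it, and the resistant-to-wild-type ratio at the end
#' of that pulse are reported.
#'
#' Pulse intervals are closed on both ends for minimum attribution; a
#' minimum falling exactly on a pulse boundary is attributed to the
#' earlier pulse. "End of the best pulse" is the boundary time closing
#' that pulse (treatment can be stopped after, but not during, a pulse),
#' not the time of the minimum itself.
#'
#' @param sequence A [pulse_sequence()].
#' @param initial Initial [population_state()]; typically the free-
#'   environment [fixed_point()].
#' @param params [model_params()].
#' @param output_step Dense-output sampling step (time units).
#' @param rtol,atol Relative/absolute solver tolerances.
#' @return An object of class `simulation_result` with elements
#'   `trajectory` (data frame `t, w, r, n, env, pulse`), `local_minima`
#'   (data frame `pulse, time, n`), `n_min`, `n_min_time`,
#'   `best_pulse_index`, `composition_end_best_pulse`, `params`,
#'   `sequence`.
#' @export
simulate_sequence <- function(sequence, initial, params = model_params(),
                              output_step = 0.01,
                              rtol = .RTOL, atol = .ATOL) {
  stopifnot(inherits(sequence, "pulse_sequence"), output_step > 0)
  segs <- sequence$segments
  state <- as_state(initial)

  nseg <- nrow(segs)
  seg_out <- vector("list", nseg)
  seg_candidates <- vector("list", nseg)
  for (j in seq_len(nseg)) {
    mat <- tryCatch(
      integrate_segment(state, segs$env[j], segs$duration[j], params,
                        output_step, rtol, atol),
      error = function(e) {
        stop(sprintf("segment %d (pulse %d, '%s'): %s",
                     j, segs$pulse[j], segs$env[j], conditionMessage(e)),
             call. = FALSE)
      })
    mat[, "t"] <- mat[, "t"] + segs$t_start[j]
    mat[nrow(mat), "t"] <- segs$t_end[j]
    seg_out[[j]] <- mat

    n <- unname(mat[, "w"] + mat[, "r"])
    i <- which.min(n)
    cand <- c(t = unname(mat[i, "t"]), n = n[i])
    if (i > 1L && i < nrow(mat)) {
      cand <- refine_interior_min(mat, i, segs$env[j], params, rtol, atol)
    }
    # segment endpoints are always eligible candidates as well
    seg_candidates[[j]] <- rbind(
      cand,
      c(t = unname(mat[1L, "t"]), n = n[1L]),
      c(t = unname(mat[nrow(mat), "t"]), n = n[nrow(mat)])
    )
    state <- mat[nrow(mat), c("w", "r")]
  }

  # assemble the dense trajectory, dropping duplicated boundary rows
  # (a boundary row keeps the earlier segment's env and pulse labels)
  keep_first <- c(TRUE, rep(FALSE, nseg - 1L))
  rows <- lapply(seq_len(nseg), function(j) {
    mat <- seg_out[[j]]
    if (!keep_first[j]) mat <- mat[-1L, , drop = FALSE]
    data.frame(t = mat[, "t"], w = mat[, "w"], r = mat[, "r"],
               n = mat[, "w"] + mat[, "r"],
               env = segs$env[j], pulse = segs$pulse[j],
               stringsAsFactors = FALSE)
  })
  trajectory <- do.call(rbind, rows)
  rownames(trajectory) <- NULL

  # per-pulse minima over closed pulse intervals: each pulse sees its own
  # segments' candidates plus the closing boundary of the previous pulse
  local_minima <- do.call(rbind, lapply(seq_len(sequence$n_pulses),
                                        function(p) {
    idx <- which(segs$pulse == p)
    cands <- do.call(rbind, seg_candidates[idx])
    if (p > 1L) {
      prev <- seg_candidates[[max(which(segs$pulse == p - 1L))]]
      cands <- rbind(cands, prev[nrow(prev), , drop = FALSE])
    }
    ord <- order(cands[, "n"], cands[, "t"])  # ties -> earlier time
    best <- cands[ord[1L], ]
    data.frame(pulse = p, time = best[["t"]], n = best[["n"]])
  }))
  rownames(local_minima) <- NULL

  best_pulse <- which.min(local_minima$n)  # ties -> earlier pulse
  end_best <- sequence$pulse_boundaries[best_pulse + 1L]
  end_row <- which(trajectory$t == end_best)
  end_row <- end_row[length(end_row)]
  w_end <- trajectory$w[end_row]
  comp <- if (w_end > 0) trajectory$r[end_row] / w_end else Inf

  structure(
    list(trajectory = trajectory,
         local_minima = local_minima,
         n_min = local_minima$n[best_pulse],
         n_min_time = local_minima$time[best_pulse],
         best_pulse_index = best_pulse,
         composition_end_best_pulse = comp,
         params = params,
         sequence = sequence),
    class = "simulation_result"
  )
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf(
    "Simulation over %d pulse(s), total duration %g:\n",
    x$sequence$n_pulses, x$sequence$total_tau))
  cat(sprintf("  n_min = %.6g at t = %.4g (pulse %d)\n",
              x$n_min, x$n_min_time, x$best_pulse_index))
  cat(sprintf("  r/w at end of best pulse = %.6g\n",
              x$composition_end_best_pulse))
  invisible(x)
}

#' Per-pulse population minima
#'
#' One entry per pulse: the lowest total population over that pulse's
#' closed time interval (boundary times eligible, ties broken toward the
#' earlier time).
#'
#' @param result A [simulate_sequence()] result.
#' @return Data frame with columns `pulse`, `time`, `n`.
#' @export
per_pulse_minima <- function(result) {
  stopifnot(inherits(result, "simulation_result"))
  result$local_minima
}

#' Composition ratio r/w at a time point
#'
#' Linearly interpolates the stored trajectory (segment boundaries are
#' stored exactly, so pulse-end ratios are exact solver values).
#'
#' @param trajectory Trajectory data frame from [simulate_sequence()], or
#'   a `simulation_result`.
#' @param time Time within the trajectory range.
#' @return The ratio `r/w` (dimensionless).
#' @export
composition_at <- function(trajectory, time) {
  if (inherits(trajectory, "simulation_result")) {
    trajectory <- trajectory$trajectory
  }
  stopifnot(is.data.frame(trajectory), length(time) == 1L)
  if (time < trajectory$t[1L] || time > trajectory$t[nrow(trajectory)]) {
    stop("time outside the trajectory range", call. = FALSE)
  }
  w <- stats::approx(trajectory$t, trajectory$w, xout = time,
                     ties = "ordered")$y
  r <- stats::approx(trajectory$t, trajectory$r, xout = time,
                     ties = "ordered")$y
  if (w == 0) {
    stop(structure(
      class = c("pulsedyn_infinite_ratio", "error", "condition"),
      list(message = "wild-type abundance is zero: ratio r/w is infinite",
           call = NULL)))
  }
  r / w
}

# ---- onset timescales ------------------------------------------------------

# minimum of n(t) for a single constant-environment run; returns list with
# time/value or signals "horizon too short" when the minimum is not interior
env_minimum <- function(state, env, horizon, params, output_step,
                        rtol = .RTOL, atol = .ATOL) {
  mat <- integrate_segment(state, env, horizon, params, output_step,
                           rtol, atol)
  n <- mat[, "w"] + mat[, "r"]
  i <- which.min(n)
  if (i == nrow(mat)) {
    stop("horizon too short: the population minimum lies at or beyond ",
         "the search horizon", call. = FALSE)
  }
  if (i == 1L) return(list(time = 0, n = n[1L]))
  best <- refine_interior_min(mat, i, env, params, rtol, atol)
  list(time = best[["t"]], n = best[["n"]])
}

#' Optimal initial low-stress duration t_o
#'
#' Simulates a pure low-stress environment from the free-environment fixed
#' point and returns the time at which the total population is minimal:
#' the wild-type decays while the resistant species, initially a tiny
#' switching-maintained minority, needs time to take over the logistic
#' pool. Initiating high stress at this time maximally exploits the
#' competition. The minimum is located to well below 1e-3 absolute
#' precision by nested refinement around the coarse-grid minimum.
#'
#' @param params [model_params()].
#' @param search_horizon Simulation horizon; must be long enough for the
#'   population to regrow, otherwise an error is raised.
#' @param output_step Coarse sampling step.
#' @return The time `t_o` (> 0).
#' @export
find_t_o <- function(params = model_params(), search_horizon = 60,
                     output_step = 0.01) {
  init <- fixed_point("free", params)
  m <- env_minimum(init, "low", search_horizon, params, output_step)
  m$time
}

#' Optimal final low-stress duration t_o_final
#'
#' Given the history `[low t_w_initial, high t_r]` entered from the free-
#' environment fixed point, returns the time into a concluding low-stress
#' window at which the total population attains its minimum — the moment
#' after which the resistant species begins to dominate regrowth. Returns
#' 0 when the population grows immediately (the resistant species already
#' dominates).
#'
#' @param params [model_params()].
#' @param t_w_initial Duration of the initial low-stress window (>= 0).
#' @param t_r Duration of the high-stress window (>= 0).
#' @param search_horizon Horizon for the concluding low-stress window.
#' @param output_step Coarse sampling step.
#' @return The time `t_o_final` (>= 0).
#' @export
find_t_o_final <- function(params = model_params(), t_w_initial = 0,
                           t_r = 0, search_horizon = 60,
                           output_step = 0.01) {
  stopifnot(t_w_initial >= 0, t_r >= 0)
  state <- fixed_point("free", params)
  if (t_w_initial > 0) {
    mat <- integrate_segment(state, "low", t_w_initial, params, output_step)
    state <- mat[nrow(mat), c("w", "r")]
  }
  if (t_r > 0) {
    mat <- integrate_segment(state, "high", t_r, params, output_step)
    state <- mat[nrow(mat), c("w", "r")]
  }
  m <- env_minimum(state, "low", search_horizon, params, output_step)
  m$time
}
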