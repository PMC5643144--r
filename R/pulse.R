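#' Single drug-pulse shape
#'
#' A pulse of total duration `tau` contains one connected high-stress
#' window of duration `t_r`, preceded and followed by low-stress waiting
#' times. The two waits are combined into a dimensionless skewness
#' `s = (t_w_initial - t_w_final) / (tau - t_r)` in `[-1, 1]`: `s = -1`
#' starts the pulse with the high-stress environment, `s = +1` ends with
#' it, `s = 0` is symmetric.
#'
#' @param tau Total pulse duration (time), > 0.
#' @param t_r Duration of the high-stress environment, `0 <= t_r <= tau`.
#' @param skew_s Skewness in `[-1, 1]`.
#' @return An object of class `pulse_shape`.
#' @export
pulse_shape <- function(tau, t_r, skew_s = 0) {
  stopifnot(is.numeric(tau), length(tau) == 1L, is.finite(tau), tau > 0,
            is.numeric(t_r), length(t_r) == 1L, is.finite(t_r),
            is.numeric(skew_s), length(skew_s) == 1L, is.finite(skew_s))
  if (t_r < 0 || t_r > tau) {
    stop("invalid pulse shape: t_r must satisfy 0 <= t_r <= tau ",
         sprintf("(got t_r = %g, tau = %g)", t_r, tau), call. = FALSE)
  }
  if (skew_s < -1 || skew_s > 1) {
    stop("invalid pulse shape: skewness must lie in [-1, 1] ",
         sprintf("(got %g)", skew_s), call. = FALSE)
  }
  structure(list(tau = tau, t_r = t_r, skew_s = skew_s),
            class = "pulse_shape")
}

#' Initial and final low-stress waiting times of a pulse
#'
#' Inverts the skewness parametrization:
#' `t_w_initial = (1 + s)(tau - t_r)/2` and
#' `t_w_final = (tau - t_r) - t_w_initial`, so the two waits sum to
#' `tau - t_r` exactly. When `t_r = tau` the pulse is pure high stress and
#' both waits are 0 for any skewness.
#'
#' @param shape A [pulse_shape()].
#' @return Named numeric vector `c(t_w_initial = , t_w_final = )`.
#' @export
wait_times <- function(shape) {
  stopifnot(inherits(shape, "pulse_shape"))
  low_total <- shape$tau - shape$t_r
  if (low_total <= 0) {
    return(c(t_w_initial = 0, t_w_final = 0))
  }
  twi <- (1 + shape$skew_s) * low_total / 2
  c(t_w_initial = twi, t_w_final = low_total - twi)
}

#' Pulse sequence: N identical pulses back to back
#'
#' Expands a single [pulse_shape()] repeated `n_pulses` times into an
#' ordered schedule of `(environment, duration)` segments
#' (`low t_w_initial`, `high t_r`, `low t_w_final` per pulse). Zero-length
#' segments are absorbed into their neighbour so the integrator never sees
#' an empty interval, and adjacent low-stress segments within one pulse
#' (the `t_r = 0` case) are merged. Segment end times are constructed from
#' rational multiples of the total duration so that the schedule ends at
#' exactly `n_pulses * tau`.
#'
#' The free environment never appears inside a schedule; it only sets the
#' initial state (see [fixed_point()]).
#'
#' @param shape A [pulse_shape()] describing one pulse.
#' @param n_pulses Positive integer number of identical pulses.
#' @return An object of class `pulse_sequence` with elements `shape`,
#'   `n_pulses`, `segments` (data frame with columns `env`, `duration`,
#'   `t_start`, `t_end`, `pulse`), `pulse_boundaries` (times 0..total) and
#'   `total_tau`.
#' @export
pulse_sequence <- function(shape, n_pulses = 1L) {
  stopifnot(inherits(shape, "pulse_shape"),
            is.numeric(n_pulses), length(n_pulses) == 1L,
            n_pulses >= 1, n_pulses == as.integer(n_pulses))
  n_pulses <- as.integer(n_pulses)
  tw <- wait_times(shape)
  total <- shape$tau * n_pulses

  # within-pulse fractional offsets of the three segment ends
  frac <- c(tw[["t_w_initial"]],
            tw[["t_w_initial"]] + shape$t_r,
            shape$tau) / shape$tau
  envs <- c("low", "high", "low")

  pulse <- rep(seq_len(n_pulses), each = 3L)
  env <- rep(envs, n_pulses)
  # end times as total * (pulse-1 + frac)/N: the final end is exactly total
  ends <- total * (rep(seq_len(n_pulses) - 1L, each = 3L) +
                     rep(frac, n_pulses)) / n_pulses

  durations <- diff(c(0, ends))
  keep <- durations > 1e-9 * shape$tau
  if (!any(keep)) stop("pulse sequence has no segments", call. = FALSE)
  # absorb slivers: dropping row j merges its interval into the next kept
  # row; if the last row is dropped, stretch the new last row to total
  env <- env[keep]; pulse <- pulse[keep]; ends <- ends[keep]
  ends[length(ends)] <- total

  # merge consecutive same-environment segments within one pulse
  # (arises only for t_r = 0: [low, low])
  same <- c(FALSE, env[-1] == env[-length(env)] &
                   pulse[-1] == pulse[-length(pulse)])
  grp <- cumsum(!same)
  env <- env[!same]
  pulse <- pulse[!same]
  ends <- as.numeric(tapply(ends, grp, max))

  segments <- data.frame(
    env = env,
    duration = diff(c(0, ends)),
    t_start = c(0, ends[-length(ends)]),
    t_end = ends,
    pulse = pulse,
    stringsAsFactors = FALSE
  )
  structure(
    list(shape = shape, n_pulses = n_pulses, segments = segments,
         pulse_boundaries = total * (0:n_pulses) / n_pulses,
         total_tau = total),
    class = "pulse_sequence"
  )
}

#' @export
print.pulse_sequence <- function(x, ...) {
  cat(sprintf(
    "Pulse sequence: %d pulse(s), per-pulse tau = %g, t_r = %g, s = %g\n",
    x$n_pulses, x$shape$tau, x$shape$t_r, x$shape$skew_s))
  cat(sprintf("  total duration %g over %d segment(s)\n",
              x$total_tau, nrow(x$segments)))
  invisible(x)
}

#' Build an N-pulse sequence at fixed total treatment time
#'
#' Compares like with like: a treatment of total duration `total_tau` and
#' total high-stress exposure `total_t_r` is split into `N` identical
#' pulses, each with `tau = total_tau / N`, `t_r = total_t_r / N` and the
#' same skewness `s`.
#'
#' @param total_tau Total treatment duration.
#' @param total_t_r Total high-stress duration, `0 <= total_t_r <= total_tau`.
#' @param s Skewness in `[-1, 1]`, shared by all pulses.
#' @param N Number of pulses (positive integer).
#' @return A [pulse_sequence()].
#' @examples
#' build_sequence(60, 6, 0, 3)  # 3 x [low 4.5, high 2, low 4.5]
#' @export
build_sequence <- function(total_tau, total_t_r, s = 0, N = 1L) {
  stopifnot(is.numeric(N), length(N) == 1L, N >= 1)
  pulse_sequence(pulse_shape(total_tau / N, total_t_r / N, s), N)
}

#' Constant drug-load specification
#'
#' When the quantity held fixed is the total drug load rather than the
#' treatment duration, `t_sum = tau + alpha * t_r` is a proxy for that
#' load, with `alpha = (MIC_r - MIC_w) / MIC_w` weighting the high-stress
#' window by how much more concentrated the drug must be.
#'
#' @param t_sum Fixed load proxy (time units), > 0.
#' @param alpha Dimensionless load weight, >= 0 (1 is the illustrative
#'   choice; 0 recovers the constant-duration comparison).
#' @return An object of class `constant_load_spec`.
#' @export
constant_load_spec <- function(t_sum, alpha = 1) {
  stopifnot(is.numeric(t_sum), length(t_sum) == 1L, t_sum > 0,
            is.numeric(alpha), length(alpha) == 1L, alpha >= 0)
  structure(list(t_sum = t_sum, alpha = alpha), class = "constant_load_spec")
}

#' Single pulse at constant drug load
#'
#' For a requested high-stress duration `t_r`, the pulse duration is
#' `tau = t_sum - alpha * t_r`; the combination is feasible only when
#' `tau >= t_r`.
#'
#' @param spec A [constant_load_spec()].
#' @param t_r High-stress duration.
#' @param s Skewness.
#' @return A single-pulse [pulse_sequence()].
#' @export
build_constant_load <- function(spec, t_r, s = 0) {
  stopifnot(inherits(spec, "constant_load_spec"))
  tau <- spec$t_sum - spec$alpha * t_r
  if (tau < t_r) {
    stop(sprintf(
      "invalid pulse shape under constant load: tau = t_sum - alpha*t_r = %g < t_r = %g",
      tau, t_r), call. = FALSE)
  }
  pulse_sequence(pulse_shape(tau, t_r, s), 1L)
}

#' Merged view of a schedule's segments
#'
#' Adjacent segments with the same environment are merged across pulse
#' boundaries, giving the minimal description of the concentration
#' profile (e.g. any sequence with `t_r = tau` collapses to one
#' high-stress segment of the full duration).
#'
#' @param sequence A [pulse_sequence()].
#' @return Data frame with columns `env` and `duration`.
#' @export
merged_segments <- function(sequence) {
  stopifnot(inherits(sequence, "pulse_sequence"))
  seg <- sequence$segments
  same <- c(FALSE, seg$env[-1] == seg$env[-nrow(seg)])
  grp <- cumsum(!same)
  data.frame(
    env = seg$env[!same],
    duration = as.numeric(tapply(seg$duration, grp, sum)),
    stringsAsFactors = FALSE
  )
}

#' Serialize a schedule to JSON
#'
#' Writes the merged `(env, duration)` segment list together with the
#' pulse boundary times.
#'
#' @param sequence A [pulse_sequence()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_schedule_json <- function(sequence, path) {
  seg <- merged_segments(sequence)
  obj <- list(
    segments = lapply(seq_len(nrow(seg)), function(i) {
      list(env = toupper(seg$env[i]), duration = seg$duration[i])
    }),
    pulse_boundaries = sequence$pulse_boundaries
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
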