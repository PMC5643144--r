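#' Stress-environment labels
#'
#' The drug concentration enters the model only through whether it exceeds
#' each species' minimum inhibitory concentration (MIC). That leaves three
#' environments: `"free"` (below both MICs, both species grow), `"low"`
#' (between the two MICs, only the resistant species grows) and `"high"`
#' (above both MICs, neither grows).
#'
#' @format Character vector of the three labels.
#' @export
ENVIRONMENTS <- c("free", "low", "high")

match_env <- function(env) {
  if (!is.character(env) || length(env) != 1L || is.na(env) ||
      !(env %in% ENVIRONMENTS)) {
    stop("unknown environment label: ", deparse(env), call. = FALSE)
  }
  env
}

# growth on/off switches (w, r) implied by an environment
env_growth_flags <- function(env) {
  switch(match_env(env),
    free = c(w = 1, r = 1),
    low  = c(w = 0, r = 1),
    high = c(w = 0, r = 0)
  )
}

#' Model parameters of the two-species birth-death system
#'
#' All rates are expressed in units of the wild-type growth rate
#' `lambda_w`, which therefore defaults to 1 (time is measured in units of
#' 1/lambda_w). The resistant species pays a growth-rate cost `cost_k` for
#' its resistance, `lambda_r = lambda_w - cost_k`. Both species die at rate
#' `delta` and switch phenotype at rates `mu_w` (wild-type to resistant)
#' and `mu_r` (resistant to wild-type).
#'
#' Defaults are the reference parameter set: `delta = 0.1`, `cost_k = 0.1`,
#' `mu_w = 1e-6`, `mu_r = 0`.
#'
#' @param lambda_w Wild-type growth rate (> 0).
#' @param cost_k Growth-rate cost of resistance, `0 <= cost_k < lambda_w`.
#' @param delta Death rate (>= 0), shared by both species.
#' @param mu_w Switching rate wild-type -> resistant (>= 0).
#' @param mu_r Switching rate resistant -> wild-type (>= 0).
#' @return An object of class `model_params` with the inputs plus the
#'   derived resistant growth rate `lambda_r`.
#' @examples
#' p <- model_params()
#' p$lambda_r  # 0.9
#' @export
model_params <- function(lambda_w = 1, cost_k = 0.1, delta = 0.1,
                         mu_w = 1e-6, mu_r = 0) {
  stopifnot(
    is.numeric(lambda_w), length(lambda_w) == 1L, lambda_w > 0,
    is.numeric(cost_k), length(cost_k) == 1L, cost_k >= 0, cost_k < lambda_w,
    is.numeric(delta), length(delta) == 1L, delta >= 0,
    is.numeric(mu_w), length(mu_w) == 1L, mu_w >= 0,
    is.numeric(mu_r), length(mu_r) == 1L, mu_r >= 0
  )
  structure(
    list(lambda_w = lambda_w, cost_k = cost_k, delta = delta,
         mu_w = mu_w, mu_r = mu_r, lambda_r = lambda_w - cost_k),
    class = "model_params"
  )
}

#' @export
print.model_params <- function(x, ...) {
  cat("Two-species model parameters (rates in units of lambda_w):\n")
  cat(sprintf("  lambda_w = %g, lambda_r = %g (cost k = %g)\n",
              x$lambda_w, x$lambda_r, x$cost_k))
  cat(sprintf("  delta = %g, mu_w = %g, mu_r = %g\n",
              x$delta, x$mu_w, x$mu_r))
  invisible(x)
}

#' Population state
#'
#' Abundances of the wild-type (`w`) and resistant (`r`) species as
#' dimensionless fractions of the carrying capacity; the total population
#' is `n = w + r`.
#'
#' @param w,r Nonnegative abundances.
#' @return Named numeric vector `c(w = , r = )`.
#' @export
population_state <- function(w, r) {
  stopifnot(is.numeric(w), length(w) == 1L, is.finite(w), w >= 0,
            is.numeric(r), length(r) == 1L, is.finite(r), r >= 0)
  c(w = as.numeric(w), r = as.numeric(r))
}

as_state <- function(state) {
  if (is.list(state)) state <- unlist(state)
  stopifnot(is.numeric(state), length(state) == 2L, all(is.finite(state)))
  setNames(as.numeric(state), c("w", "r"))
}

#' Per-capita growth rate of one species in a given environment
#'
#' The drug is bacteriostatic: growth ceases abruptly once the
#' concentration exceeds a species' MIC. Below the MIC the species grows
#' logistically against the shared pool, `lambda_eta * (1 - w - r)`. The
#' returned rate is therefore 0 whenever the environment is at or above
#' the species' MIC, and may be negative when the population exceeds the
#' carrying capacity (n > 1).
#'
#' @param env Environment label, one of [ENVIRONMENTS].
#' @param species `"w"` or `"r"`.
#' @param state Population state, see [population_state()].
#' @param params [model_params()].
#' @return Growth rate in 1/time.
#' @export
growth_rate <- function(env, species, state, params = model_params()) {
  species <- match.arg(species, c("w", "r"))
  state <- as_state(state)
  flags <- env_growth_flags(env)
  lambda <- if (species == "w") params$lambda_w else params$lambda_r
  flags[[species]] * lambda * (1 - state[["w"]] - state[["r"]])
}

#' Right-hand side of the population dynamics
#'
#' Time derivatives of the two abundances:
#' \deqn{\dot w = [\phi_w - \delta - \mu_w] w + \mu_r r}
#' \deqn{\dot r = \mu_w w + [\phi_r - \delta - \mu_r] r}
#' with the environment-dependent logistic growth rates \eqn{\phi_\eta}
#' from [growth_rate()].
#'
#' @inheritParams growth_rate
#' @return Named numeric vector `c(w = dw/dt, r = dr/dt)`.
#' @export
rhs <- function(env, state, params = model_params()) {
  state <- as_state(state)
  w <- state[["w"]]; r <- state[["r"]]
  phi_w <- growth_rate(env, "w", state, params)
  phi_r <- growth_rate(env, "r", state, params)
  c(w = (phi_w - params$delta - params$mu_w) * w + params$mu_r * r,
    r = params$mu_w * w + (phi_r - params$delta - params$mu_r) * r)
}

# analytic Jacobian of rhs at a state (2x2 matrix)
rhs_jacobian <- function(env, state, params) {
  flags <- env_growth_flags(env)
  w <- state[[1]]; r <- state[[2]]
  gw <- flags[["w"]] * params$lambda_w
  gr <- flags[["r"]] * params$lambda_r
  matrix(c(
    gw * (1 - 2 * w - r) - params$delta - params$mu_w,  # d wdot / d w
    params$mu_w - gr * r,                               # d rdot / d w
    -gw * w + params$mu_r,                              # d wdot / d r
    gr * (1 - w - 2 * r) - params$delta - params$mu_r   # d rdot / d r
  ), nrow = 2)
}

#' Stable fixed point of an environment
#'
#' Locates the stable nonzero stationary state of the dynamics in the
#' `"free"` environment (near the w axis: the faster-growing wild-type
#' dominates, with a small resistant fraction maintained by switching) or
#' the `"low"` environment (on/near the r axis: only the resistant species
#' grows). For `"high"` the only fixed point is extinction, `(0, 0)`.
#'
#' The root of [rhs()] is found by Newton iteration with the analytic
#' Jacobian, seeded from the `mu = 0` logistic-with-death closed forms
#' (`w* = 1 - delta/lambda_w` resp. `r* = 1 - delta/lambda_r`, with the
#' minority species seeded from a linearization in the switching rate);
#' convergence requires a residual norm below 1e-12.
#'
#' @inheritParams growth_rate
#' @param tol Absolute residual tolerance on the root.
#' @return A [population_state()].
#' @export
fixed_point <- function(env, params = model_params(), tol = 1e-12) {
  env <- match_env(env)
  if (env == "high") return(population_state(0, 0))

  lambda_major <- if (env == "free") params$lambda_w else params$lambda_r
  if (params$delta >= lambda_major) {
    stop("population not viable in this environment: delta >= ",
         "growth rate of the surviving species", call. = FALSE)
  }
  major <- 1 - params$delta / lambda_major

  if (env == "free") {
    # minority r maintained by mu_w against net decay at the majority point
    denom <- params$delta + params$mu_r - params$lambda_r * (1 - major)
    r0 <- if (params$mu_w == 0) 0 else params$mu_w * major / max(denom, 1e-8)
    x <- c(major, r0)
  } else {
    denom <- params$delta + params$mu_w
    w0 <- if (params$mu_r == 0) 0 else params$mu_r * major / max(denom, 1e-8)
    x <- c(w0, major)
  }

  for (iter in 1:100) {
    f <- rhs(env, x, params)
    if (sqrt(sum(f^2)) < tol) break
    step <- tryCatch(solve(rhs_jacobian(env, x, params), f),
                     error = function(e) NULL)
    if (is.null(step)) {
      stop("fixed-point search failed: singular Jacobian in environment ",
           env, call. = FALSE)
    }
    x <- x - step
  }
  f <- rhs(env, x, params)
  if (sqrt(sum(f^2)) >= tol || any(!is.finite(x))) {
    stop("fixed-point search did not converge in environment ", env,
         call. = FALSE)
  }
  if (sum(x) <= tol) {
    stop("population not viable in this environment: only the extinct ",
         "state is stationary", call. = FALSE)
  }
  population_state(max(x[1], 0), max(x[2], 0))
}
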