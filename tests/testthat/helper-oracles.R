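# Closed-form solutions used as independent oracles against the integrator.

# high environment, mu_r = 0: both species only die; switching moves
# abundance from w to r but conserves n up to the death term
high_closed_form <- function(w0, r0, t, delta, mu_w) {
  w <- w0 * exp(-(delta + mu_w) * t)
  r <- exp(-delta * t) * (r0 + w0 * (1 - exp(-mu_w * t)))
  cbind(w = w, r = r)
}

# low environment, mu_r = 0: w receives nothing back and cannot grow
low_w_closed_form <- function(w0, t, delta, mu_w) {
  w0 * exp(-(delta + mu_w) * t)
}

default_params <- function() model_params()

# free-environment fixed point at the default parameter set, computed once
free_state <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- fixed_point("free", model_params())
    cache
  }
})
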