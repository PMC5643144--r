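# Coarse grids keep these structural checks cheap; the full-resolution
# landscape is exercised by the acceptance suite.

coarse_sweep <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      grid <- sweep_grid(60, t_r_values = seq(5, 55, by = 10),
                         s_values = seq(-1, 1, by = 0.25), N_values = 1:3)
      cache <<- run_sweep(grid, model_params(), output_step = 0.05)
    }
    cache
  }
})

test_that("cells without high stress are independent of s and N", {
  grid <- sweep_grid(60, t_r_values = 0, s_values = c(-0.5, 0, 1),
                     N_values = 1:3)
  cells <- run_sweep(grid, model_params(), output_step = 0.05)
  ref <- simulate_sequence(build_sequence(60, 0, 0, 1), free_state(),
                           model_params(), output_step = 0.05)
  expect_lt(max(abs(cells$n_min - ref$n_min)) / ref$n_min, 1e-9)
})

test_that("n_min is non-increasing in t_r at fixed s and N", {
  cells <- coarse_sweep()
  for (d in split(cells, list(cells$s, cells$N))) {
    d <- d[order(d$t_r), ]
    expect_true(all(diff(d$n_min) <= 1e-9 * d$n_min[-nrow(d)]))
  }
})

test_that("n_min saturates in t_r once the decay window is exhausted", {
  # below the saturation point extra high-stress time still pays off
  # (changes of several percent per unit t_r); once the shrinking final
  # wait falls below the resistant takeover time the population decays
  # for the whole pulse and n_min flattens
  p <- model_params()
  fp <- free_state()
  nm <- vapply(c(41:43, 57:59), function(tr) {
    simulate_sequence(build_sequence(60, tr, -0.5, 1), fp, p)$n_min
  }, numeric(1))
  unsaturated <- abs(diff(nm[1:3])) / nm[2:3]
  saturated <- abs(diff(nm[4:6])) / nm[5:6]
  expect_true(all(unsaturated > 1e-2))
  expect_true(all(saturated < 1e-3))
})

test_that("the winning-N map breaks ties toward the simpler treatment", {
  # at t_r = tau every N gives the same pure high-stress schedule
  grid <- sweep_grid(60, t_r_values = 60, s_values = 0, N_values = 1:4)
  cells <- run_sweep(grid, model_params(), output_step = 0.05)
  bm <- best_sequence_map(cells)
  expect_equal(nrow(bm), 1L)
  expect_equal(bm$best_N, 1L)
  expect_true(cells$is_best_N[cells$N == 1])
  expect_false(any(cells$is_best_N[cells$N > 1]))

  # degenerate 1x1 grid reduces to a single simulation's observables
  grid1 <- sweep_grid(60, t_r_values = 30, s_values = 0.2, N_values = 2)
  cells1 <- run_sweep(grid1, model_params(), output_step = 0.05)
  ref <- simulate_sequence(build_sequence(60, 30, 0.2, 2), free_state(),
                           model_params(), output_step = 0.05)
  expect_equal(cells1$n_min, ref$n_min)
  expect_equal(cells1$best_pulse_index, ref$best_pulse_index)

  # first/last-pulse attribution flags match the landscape structure
  bm <- best_sequence_map(coarse_sweep())
  corner_last <- bm[bm$t_r == 55 & bm$s == -1, ]
  expect_true(all(corner_last$min_in_last_pulse))
  corner_first <- bm[bm$t_r == 5 & bm$s == 1, ]
  expect_true(all(corner_first$min_in_first_pulse))
})

test_that("the optimal-skewness line tracks the onset-time prediction", {
  p <- model_params()
  grid <- sweep_grid(60, t_r_values = c(5, 10),
                     s_values = seq(-1, 1, by = 0.05), N_values = 1)
  cells <- run_sweep(grid, p, output_step = 0.05)
  t_o <- find_t_o(p)
  line <- optimal_skewness_line(cells, N = 1, total_tau = 60, t_o = t_o)
  # grid argmin lands within one grid step of 2 t_o / (tau - t_r) - 1
  expect_true(all(abs(line$s_opt - line$s_opt_predicted) <= 0.05 + 1e-12))
  expect_equal(line$s_opt_predicted,
               2 * t_o / (60 - line$t_r) - 1, tolerance = 1e-12)
})

test_that("sweeps are deterministic and reproducible bit for bit", {
  grid <- sweep_grid(60, t_r_values = c(10, 30), s_values = c(-0.5, 0.5),
                     N_values = 1:2)
  a <- run_sweep(grid, model_params(), output_step = 0.05)
  b <- run_sweep(grid, model_params(), output_step = 0.05)
  expect_identical(a, b)

  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_sweep_csv(a, f1)
  write_sweep_csv(b, f2)
  expect_identical(readLines(f1), readLines(f2))

  # full-precision CSV round-trips every double exactly
  back <- read_sweep_csv(f1)
  expect_identical(back$n_min, a$n_min)
  expect_identical(back$r_over_w_end, a$r_over_w_end)
  expect_equal(back, a, ignore_attr = TRUE)
})

test_that("constant-load sweeps reduce to constant-tau at alpha = 0 and warn when infeasible", {
  p <- model_params()
  s_vals <- c(-0.5, 0, 0.5)
  cl <- constant_load_sweep(constant_load_spec(60, 0), c(10, 30), s_vals, p,
                            output_step = 0.05)
  grid <- sweep_grid(60, t_r_values = c(10, 30), s_values = s_vals,
                     N_values = 1)
  ct <- run_sweep(grid, p, output_step = 0.05)
  expect_equal(cl$n_min, ct$n_min)
  expect_equal(cl$r_over_w_end, ct$r_over_w_end)

  # at alpha = 1 only t_r <= t_sum / 2 is feasible
  expect_warning(
    cl1 <- constant_load_sweep(constant_load_spec(60, 1), c(10, 30, 40),
                               0, p, output_step = 0.05),
    "infeasible")
  expect_equal(unique(cl1$t_r), c(10, 30))
  expect_equal(cl1$tau, 60 - cl1$t_r)
})

test_that("best-N regions are stable under grid refinement", {
  p <- model_params()
  coarse <- run_sweep(sweep_grid(60, seq(5, 55, by = 10),
                                 seq(-1, 1, by = 0.25), 1:3),
                      p, output_step = 0.05)
  fine <- run_sweep(sweep_grid(60, seq(5, 55, by = 5),
                               seq(-1, 1, by = 0.125), 1:3),
                    p, output_step = 0.05)
  bc <- best_sequence_map(coarse)
  bf <- best_sequence_map(fine)
  merged <- merge(bc, bf, by = c("t_r", "s"), suffixes = c("_c", "_f"))
  expect_equal(nrow(merged), nrow(bc))
  frac_changed <- mean(merged$best_N_c != merged$best_N_f)
  expect_lte(frac_changed, 0.05)
})
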