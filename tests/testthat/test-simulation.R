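test_that("noise drive is a reproducible zero-order hold with the stated moments", {
  cfg <- simulation_config(duration = 30, n_repeats = 1, seed = 7)
  drv <- make_drive(cfg, mu_r = 86, phi_r = 1, repeat_index = 1)
  vals <- attr(drv, "values")
  expect_length(vals, 30000)
  # hold semantics: constant within a step, new value at the next step
  expect_identical(drv(0), drv(0.0005))
  expect_identical(drv(0.001), vals[2])
  expect_identical(drv(c(0, 0.0024)), vals[c(1, 3)])
  # reproducibility from (seed, repeat)
  drv2 <- make_drive(cfg, 86, 1, repeat_index = 1)
  expect_identical(attr(drv2, "values"), vals)
  expect_false(identical(attr(make_drive(cfg, 86, 1, 2), "values"), vals))
  # CLT bound on the sample mean over 30,000 steps
  expect_lt(abs(mean(vals) - 86), 3 * sqrt(1 / 30000))
  # zero variance degenerates to the constant drive
  expect_identical(attr(make_drive(cfg, 86, 0, 1), "values"), rep(86, 30000))
  expect_error(make_drive(cfg, 86, -1, 1), "phi_r")
})

test_that("the drive-free system relaxes to the root-found fixed point", {
  p <- model_parameters(mu_r = 0, phi_r = 0)
  cfg <- quick_sim(duration = 5, n_repeats = 1)
  tr <- integrate_model(p, cfg, drive = function(t) rep(0, length(t)),
                        full_state = TRUE)
  fp <- fixed_point(p, drive = 0)
  expect_equal(unname(tr$state[nrow(tr$state), ]), unname(fp),
               tolerance = 1e-8)
  last_sec <- tr$v[tr$time >= max(tr$time) - 1]
  expect_lt(sd(last_sec), 1e-6)
  expect_equal(tr$v[length(tr$v)], output_potential(fp, p), tolerance = 1e-8)
})

test_that("the noise-free limit is seed-independent", {
  p <- model_parameters(mu_r = 86, phi_r = 0)
  a <- run_repeats(p, quick_sim(duration = 4, n_repeats = 2, seed = 1))
  b <- run_repeats(p, quick_sim(duration = 4, n_repeats = 2, seed = 99))
  expect_identical(a$traces, b$traces)
  # repeats within one run are identical too: across-repeat variance is 0
  expect_identical(a$traces[, 1], a$traces[, 2])
})

test_that("halving the step barely changes the trajectory (same held noise)", {
  p <- model_parameters()
  cfg1 <- quick_sim(duration = 6, n_repeats = 1, seed = 3)
  drv <- make_drive(cfg1, p$mu_r, p$phi_r, 1)      # noise held at 1 ms
  cfg2 <- simulation_config(duration = 6, dt = 5e-4, n_repeats = 1, seed = 3)
  tr1 <- integrate_model(p, cfg1, drv)
  tr2 <- integrate_model(p, cfg2, drv)
  v2 <- tr2$v[seq(1, length(tr2$v), by = 2)]       # common time points
  post <- tr1$time >= 2
  rel_rms <- sqrt(mean((tr1$v[post] - v2[post])^2)) /
    sqrt(mean(tr1$v[post]^2))
  expect_lt(rel_rms, 0.01)
})

test_that("adaptive rk45 over the same held noise tracks the rk4 reference", {
  p <- model_parameters(phi_r = 0)
  cfg <- quick_sim(duration = 3, n_repeats = 1)
  tr4 <- integrate_model(p, cfg, method = "rk4")
  tr45 <- integrate_model(p, cfg, method = "rk45")
  post <- tr4$time >= 1
  rel_rms <- sqrt(mean((tr4$v[post] - tr45$v[post])^2)) /
    sqrt(mean(tr4$v[post]^2))
  expect_lt(rel_rms, 0.02)
})

test_that("repeat management averages, seeds and reproduces exactly", {
  p <- model_parameters()
  one <- run_repeats(p, quick_sim(duration = 4, n_repeats = 1, seed = 5))
  expect_identical(one$mean_trace, one$traces[, 1])
  multi <- run_repeats(p, quick_sim(duration = 4, n_repeats = 3, seed = 5))
  expect_equal(multi$mean_trace, rowMeans(multi$traces), tolerance = 1e-12)
  expect_identical(multi$seeds, 5L + 1:3)
  expect_identical(multi$tau_i_used, p$tau_i)
  # transient discard
  expect_equal(min(multi$time), 2)
  # bitwise reproducibility of the whole result
  again <- run_repeats(p, quick_sim(duration = 4, n_repeats = 3, seed = 5))
  expect_identical(multi$traces, again$traces)
})

test_that("divergence is reported with the failing time and repeat", {
  p <- model_parameters()
  cfg <- quick_sim(duration = 3, n_repeats = 2, divergence_bound = 1e-4)
  expect_error(run_repeats(p, cfg), "diverged at t = .*repeat 1")
  expect_error(
    integrate_model(p, quick_sim(duration = 3, n_repeats = 1,
                                 divergence_bound = 1e-4)),
    "diverged")
})

test_that("the study's whole parameter envelope integrates stably", {
  corners <- list(
    list(beta = 5.0, C1 = 100, mu = 100),
    list(beta = 0.0, C1 = 0, mu = 0),
    list(beta = 2.10, C1 = 100, mu = 0),
    list(beta = 5.0, C1 = 0, mu = 100))
  for (cs in corners) {
    p <- model_parameters(tau_i = tau_inhibitory(cs$beta), C1 = cs$C1,
                          mu_r = cs$mu)
    sim <- run_repeats(p, quick_sim(duration = 3, n_repeats = 1))
    expect_true(all(is.finite(sim$traces)))
  }
})

test_that("configuration invariants are enforced", {
  expect_error(simulation_config(dt = 0), "dt")
  expect_error(simulation_config(dt = 40, duration = 30), "dt")
  expect_error(simulation_config(transient = 31, duration = 30), "transient")
  expect_error(simulation_config(n_repeats = 0), "n_repeats")
  expect_error(simulation_config(initial_state = rep(NA_real_, 6)), "finite")
})
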