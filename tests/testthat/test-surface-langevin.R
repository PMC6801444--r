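test_that("barrier preset is periodic, finite, and calibrated to its saddle height", {
  s <- ref_surface("barrier", saddle_height = 4.3, saddle_dz = 1.8,
                   saddle_theta = 150)
  dz <- seq(0.8, 3.0, length.out = 60)
  th <- seq(-360, 720, length.out = 61)
  expect_true(all(is.finite(outer(dz, th, function(d, t)
    surface_energy(s, d, t)))))
  expect_equal(surface_energy(s, dz, th[1:60]),
               surface_energy(s, dz, th[1:60] + 360), tolerance = 1e-12)
  # minimum-over-paths maximum between basins, by dense grid search
  rb <- surface_ref_barrier(s, n_dz = 201, n_theta = 121)
  expect_equal(rb$barrier, 4.3, tolerance = 0.02)
  expect_equal(unname(rb$saddle["dz"]), 1.8, tolerance = 0.03)
  expect_equal(unname(rb$saddle["theta"]), 150, tolerance = 5)
})

test_that("downhill preset is a single funnel with a negligible barrier", {
  s <- ref_surface("downhill")
  rb <- surface_ref_barrier(s, n_dz = 151, n_theta = 73)
  expect_lt(rb$barrier, 0.05)
  # free energy decreases monotonically along the valley
  dz <- seq(2.4, 1.25, length.out = 100)
  v <- surface_energy(s, dz, chiradsorb:::.theta_star(s, dz))
  expect_true(all(diff(v) < 1e-9))
})

test_that("downhill Langevin traces adsorb within the trace span", {
  tr <- simulate_traces(ref_surface("downhill"), langevin_config(seed = 5),
                        n_traj = 25)
  fp <- fpt_samples(tr, 1.5)
  expect_gte(mean(!fp$censored), 0.95)
  expect_true(all(fp$value > 0))
  expect_true(all(!is.na(unlist(lapply(tr, `[[`, "theta")))))
  th <- unlist(lapply(tr, `[[`, "theta"))
  expect_true(all(th >= 0 & th < 360))
})

test_that("the barrier preset produces a slower FPT tail than the downhill preset", {
  cfg <- langevin_config(seed = 8)
  fp_down <- fpt_samples(simulate_traces(ref_surface("downhill"), cfg, 40),
                         1.5)
  s_bar <- ref_surface("barrier")
  cfg_b <- langevin_config(seed = 8,
                           init = list(dz = c(2.2, 0.03), theta = NULL))
  fp_bar <- fpt_samples(simulate_traces(s_bar, cfg_b, 40), 1.5)
  # survival at the downhill 90% quantile: much heavier tail with a barrier
  q <- quantile(fp_down$value[!fp_down$censored], 0.9)
  surv_bar <- mean(fp_bar$value > q)
  expect_gt(surv_bar, 2 * 0.1)
})

test_that("flat surface at zero temperature leaves dz constant", {
  cfg <- langevin_config(total_time = 2, temperature = 0, seed = 1,
                         init = list(dz = c(1.8, 0), theta = c(90, 0)))
  tr <- simulate_traces(ref_surface("flat"), cfg, n_traj = 3)
  for (t in tr) expect_equal(diff(range(t$dz)), 0)
})

test_that("Langevin sampler reproduces the harmonic stationary variance kBT/kappa", {
  kappa <- 10
  s <- ref_surface("harmonic", harmonic_kappa = kappa)
  cfg <- langevin_config(total_time = 100, dt = 0.005, d_dz = 0.2, seed = 2,
                         init = list(dz = c(1.75, 0.1), theta = c(180, 10)))
  tr <- simulate_traces(s, cfg, n_traj = 200)
  dzs <- unlist(lapply(tr, function(t) t$dz[2001:20001]))
  expect_equal(var(dzs) * kappa, 1, tolerance = 0.02)
})

test_that("seeded trace generation is bit-reproducible", {
  s <- ref_surface("downhill")
  cfg <- langevin_config(total_time = 5, seed = 31)
  t1 <- simulate_traces(s, cfg, n_traj = 3)
  t2 <- simulate_traces(s, cfg, n_traj = 3)
  expect_identical(lapply(t1, `[[`, "dz"), lapply(t2, `[[`, "dz"))
  expect_identical(lapply(t1, `[[`, "theta"), lapply(t2, `[[`, "theta"))
})

test_that("langevin_config validates its discretization", {
  expect_error(langevin_config(dt = 0), "positive")
  expect_error(langevin_config(dt = 0.3, total_time = 1), "integer")
})

test_that("umbrella sampler is seed-reproducible with overlapping windows", {
  s <- ref_surface("barrier")
  u1 <- sample_umbrella(s, centers = seq(1.4, 2.2, length.out = 5),
                        n_samples = 1200, seed = 4)
  u2 <- sample_umbrella(s, centers = seq(1.4, 2.2, length.out = 5),
                        n_samples = 1200, seed = 4)
  expect_identical(u1$windows[[3]]$samples, u2$windows[[3]]$samples)
  expect_true(all(u1$overlap > 0.01))
  expect_error(sample_umbrella(s, centers = c(1.5, 1.4)), "increasing")
})

test_that("a single flat-surface window samples around its center", {
  s <- ref_surface("flat")
  u <- sample_umbrella(s, centers = 1.75, n_samples = 8000, seed = 6)
  dz <- u$windows[[1]]$samples$dz
  sigma <- sqrt(chiradsorb:::kBT_kJmol(303.15) / 1000)
  expect_equal(mean(dz), 1.75, tolerance = 4 * sigma / sqrt(200))
})
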