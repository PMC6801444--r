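# exact-sampling umbrella set on a harmonic target: the biased density of
# window k is Gaussian with known mean and variance, so samples can be drawn
# iid and the recovered PMF compared against the closed-form surface
exact_harmonic_windows <- function(kU = 5, d0 = 1.75, centers, k_bias = 1000,
                                   n = 20000, seed = 1, temperature = 303.15) {
  kb <- k_bias / chiradsorb:::kBT_kJmol(temperature)  # kBT/nm^2
  set.seed(seed)
  windows <- lapply(centers, function(cc) {
    prec <- kU + kb
    mu <- (kU * d0 + kb * cc) / prec
    list(center = cc,
         samples = data.frame(dz = rnorm(n, mu, sqrt(1 / prec)),
                              theta = runif(n, 0, 360)),
         acceptance = 1)
  })
  structure(list(windows = windows, centers = centers, k_bias = k_bias,
                 temperature = temperature, seed = seed, burn_in = 0,
                 n_chains = 1, bias_offset = rep(0, length(centers))),
            class = "umbrella_set")
}

test_that("reweighting recovers a closed-form harmonic PMF within 0.1 kBT RMS", {
  centers <- seq(1.45, 2.05, length.out = 7)
  uws <- exact_harmonic_windows(centers = centers, seed = 2)
  fit <- estimate_pmf(uws, subsample = FALSE)
  prof <- fit$one_d
  counts <- tapply(rep(1, nrow(fit$samples)),
                   findInterval(fit$samples$dz, fit$dz_edges), sum)
  well <- prof[prof$dz > 1.45 & prof$dz < 2.05, ]
  ref <- 5 / 2 * (well$dz - 1.75)^2
  ref <- ref - min(ref)
  well$F <- well$F - min(well$F)
  expect_lt(sqrt(mean((well$F - ref)^2)), 0.1)
})

test_that("PMF error shrinks roughly by half when samples quadruple", {
  centers <- seq(1.45, 2.05, length.out = 7)
  rms_at <- function(n, seed) {
    uws <- exact_harmonic_windows(centers = centers, n = n, seed = seed)
    prof <- estimate_pmf(uws, subsample = FALSE)$one_d
    well <- prof[prof$dz > 1.45 & prof$dz < 2.05, ]
    ref <- 5 / 2 * (well$dz - 1.75)^2
    sqrt(mean(((well$F - min(well$F)) - (ref - min(ref)))^2))
  }
  r1 <- mean(sapply(1:3, function(s) rms_at(500, s)))
  r4 <- mean(sapply(1:3, function(s) rms_at(8000, s)))
  expect_lt(r4, 0.75 * r1)
})

test_that("WHAM and MBAR agree bin-wise within 0.2 kBT", {
  s <- ref_surface("barrier")
  uws <- sample_umbrella(s, centers = seq(1.0, 2.5, length.out = 10),
                         n_samples = 5000, seed = 12)
  fm <- estimate_pmf(uws, estimator = "mbar")
  fw <- estimate_pmf(uws, estimator = "wham")
  both <- fm$mask & fw$mask
  expect_gt(sum(both), 50)
  expect_lt(max(abs(fm$F[both] - fw$F[both])), 0.2)
})

test_that("the PMF is gauge invariant under per-window bias offsets", {
  centers <- seq(1.55, 1.95, length.out = 5)
  uws <- exact_harmonic_windows(centers = centers, n = 4000, seed = 3)
  f0 <- estimate_pmf(uws, subsample = FALSE, tol = 1e-12)
  uws$bias_offset <- c(2.5, -1, 0.5, 3, -2)
  f1 <- estimate_pmf(uws, subsample = FALSE, tol = 1e-12)
  expect_lt(max(abs(f0$F[f0$mask] - f1$F[f1$mask])), 1e-8)
  expect_lt(max(abs(f0$one_d$F - f1$one_d$F)), 1e-8)
})

test_that("single flat window gives a flat PMF; gaps between windows error", {
  s <- ref_surface("flat")
  uws <- sample_umbrella(s, centers = 1.75, n_samples = 6000, seed = 4)
  fit <- estimate_pmf(uws)
  prof <- fit$one_d
  core <- prof[abs(prof$dz - 1.75) < 0.065, ]  # well-populated bins
  expect_lt(diff(range(core$F)), 0.35)
  # non-overlapping windows are a named error
  uws2 <- exact_harmonic_windows(centers = c(1.2, 2.3), n = 2000, seed = 5)
  expect_error(estimate_pmf(uws2, subsample = FALSE), "overlap")
})

test_that("reweighted expectations are normalized and bin consistent", {
  centers <- seq(1.5, 2.0, length.out = 6)
  uws <- exact_harmonic_windows(centers = centers, n = 5000, seed = 6)
  fit <- estimate_pmf(uws, subsample = FALSE)
  one <- reweighted_expectation(uws, function(dz, th) rep(1, length(dz)),
                                fit = fit)
  expect_true(all(abs(one$mean - 1) < 1e-12))
  expect_true(all(one$sd < 1e-6))
  ez <- reweighted_expectation(uws, function(dz, th) dz, fit = fit)
  ib <- findInterval(ez$dz, fit$dz_edges)
  expect_true(all(ez$mean >= fit$dz_edges[ib] - 1e-9))
  expect_true(all(ez$mean <= fit$dz_edges[ib + 1] + 1e-9))
  # a planted theta-linked observable matches its analytic expectation:
  # theta is uniform and independent of dz here, so E[cos theta | dz] = 0
  ct <- reweighted_expectation(uws, function(dz, th) cos(th * pi / 180),
                               fit = fit)
  big <- ct[ct$n_eff > 2000, ]
  expect_true(all(abs(big$mean) < 4 / sqrt(big$n_eff / 2)))
})

test_that("minimax path height is direction invariant and the barrier finder works", {
  s <- ref_surface("barrier")
  uws <- sample_umbrella(s, n_samples = 6000, seed = 13)
  fit <- estimate_pmf(uws)
  br <- find_barrier(fit, c(2.2, 90), c(1.2, 230))
  expect_gte(br$barrier, 0)
  expect_equal(unname(br$saddle["dz"]), 1.8, tolerance = 0.15)
  # direction invariance of the minimax height
  rev <- find_barrier(fit, c(1.2, 230), c(2.2, 90))
  expect_equal(max(br$path$F), max(rev$path$F), tolerance = 1e-12)
  # saddle lies on the path; path endpoints are the basins
  expect_true(any(abs(br$path$F - br$saddle["F"]) < 1e-12))
  # downhill surface: barrier below 0.3 kBT
  sd_ <- ref_surface("downhill")
  uwd <- sample_umbrella(sd_, n_samples = 6000, seed = 14)
  fd <- estimate_pmf(uwd)
  brd <- find_barrier(fd, c(2.2, 270), c(1.2, 130))
  expect_lt(brd$barrier, 0.3)
})
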