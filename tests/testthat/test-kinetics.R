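mk_trace <- function(time, dz) {
  structure(list(time = time, dz = dz, theta = rep(0, length(time)),
                 traj_id = 1L, seed = NA, dt = NA, aborted = FALSE,
                 abort_step = NA_integer_),
            class = "kinetic_trace")
}

test_that("FPT extraction interpolates, censors, and honors boundaries", {
  # dz 2.0 -> 1.4 linearly over 10 ns, threshold 1.5: crossing at 25/3 ns
  tr <- mk_trace(seq(0, 10, by = 1), seq(2.0, 1.4, by = -0.06))
  f <- extract_fpt(tr, 1.5)
  expect_equal(f$value, 25 / 3, tolerance = 1e-9)
  expect_false(f$censored)
  # never crossing: censored at the end time
  tr2 <- mk_trace(0:10, seq(2.0, 1.62, length.out = 11))
  f2 <- extract_fpt(tr2, 1.5)
  expect_true(f2$censored)
  expect_equal(f2$value, 10)
  # touching the threshold exactly counts as crossing
  tr3 <- mk_trace(0:10, c(seq(2.0, 1.51, length.out = 7), 1.5, 1.6, 1.7,
                          1.8))
  expect_equal(extract_fpt(tr3, 1.5)$value, 7)
  # starting below: zero with a flag
  tr4 <- mk_trace(0:5, rep(1.2, 6))
  f4 <- extract_fpt(tr4, 1.5)
  expect_equal(f4$value, 0)
  expect_true(f4$start_below)
  expect_error(extract_fpt(mk_trace(0, 2.0), 1.5), "fewer than 2")
})

test_that("empirical CCD is the product-limit estimator", {
  # uncensored {1,2,3}: complement of the ECDF
  cc <- empirical_ccd(c(1, 2, 3))
  expect_equal(cc$fn(1.5), 2 / 3)
  expect_equal(cc$fn(2.5), 1 / 3)
  # {1, 2+, 3}: S = 2/3 on [1, 3), 0 at 3 (survfit as oracle)
  cc2 <- empirical_ccd(data.frame(value = c(1, 2, 3),
                                  censored = c(FALSE, TRUE, FALSE)))
  expect_equal(cc2$fn(2.9), 2 / 3)
  expect_equal(cc2$fn(3), 0)
  # large-sample analytic limit: S(tau) ~ exp(-1)
  set.seed(5)
  cc3 <- empirical_ccd(rexp(20000, 1 / 10))
  expect_equal(cc3$fn(10), exp(-1), tolerance = 0.02)
  expect_warning(
    empirical_ccd(data.frame(value = c(1, 2), censored = c(TRUE, TRUE))),
    "censored")
})

test_that("exp1 MLE equals the closed form and handles censoring", {
  set.seed(10)
  x <- rexp(500, 1 / 7)
  f <- fit_ccd(x, "exp1")
  expect_equal(unname(coef(f)["tau"]), mean(x), tolerance = 1e-10)
  # with censoring: total observed time over event count
  s <- data.frame(value = c(x, rep(12, 100)),
                  censored = c(rep(FALSE, 500), rep(TRUE, 100)))
  fc <- fit_ccd(s, "exp1")
  expect_equal(unname(coef(fc)["tau"]), sum(s$value) / 500,
               tolerance = 1e-10)
  expect_error(fit_ccd(x[1:3], "exp1"), "at least 5")
})

test_that("exp1 estimator is nearly unbiased at 25 trajectories", {
  set.seed(20)
  tau <- 19.61
  est <- replicate(1000, mean(rexp(25, 1 / tau)))
  expect_lt(abs(mean(est) - tau) / tau, 0.05)
})

test_that("two-exponential fit recovers a planted mixture and flags degeneracy", {
  set.seed(30)
  n <- 4000
  fast <- runif(n) < 0.85
  y <- ifelse(fast, rexp(n, 1 / 5), rexp(n, 1 / 60))
  f <- fit_ccd(y, "exp2")
  expect_false(f$degenerate)
  expect_lt(abs(coef(f)["tau_slow"] - 60), 3 * f$se["tau_slow"])
  expect_lt(abs(coef(f)["weight_fast"] - 0.85),
            3 * f$se["weight_fast"])
  expect_lte(coef(f)["weight_fast"], 1)
  expect_gte(coef(f)["weight_fast"], 0)
  # on pure single-exponential data the mixture degenerates
  set.seed(31)
  z <- rexp(2000, 1 / 10)
  f1 <- suppressWarnings(fit_ccd(z, "exp2"))
  expect_true(f1$degenerate || coef(f1)["weight_fast"] > 0.98 ||
                coef(f1)["weight_fast"] < 0.02)
  expect_error(fit_ccd(z[1:8], "exp2"), "at least 10")
})

test_that("mixture recovery error decreases with sample size", {
  err <- sapply(c(400, 6400), function(n) {
    e <- sapply(1:4, function(r) {
      set.seed(100 * n + r)
      fast <- runif(n) < 0.9
      y <- ifelse(fast, rexp(n, 1 / 19.59), rexp(n, 1 / 117.4))
      f <- fit_ccd(y, "exp2")
      abs(coef(f)["tau_slow"] - 117.4) / 117.4 +
        abs(coef(f)["weight_fast"] - 0.9)
    })
    mean(e)
  })
  expect_lt(err[2], err[1])
})

test_that("gamma fit beats exp1 on gamma data and fitted CCDs are valid survivals", {
  set.seed(40)
  g <- rgamma(2000, shape = 2.5, scale = 8)
  fg <- fit_ccd(g, "gamma")
  f1 <- fit_ccd(g, "exp1")
  expect_lt(AIC(logLik(fg)), AIC(logLik(f1)))
  expect_equal(unname(coef(fg)["shape"]), 2.5, tolerance = 0.2)
  for (f in list(fg, f1)) {
    tt <- seq(0, max(g), length.out = 300)
    s <- predict(f, tt)
    expect_equal(s[1], 1)
    expect_true(all(diff(s) <= 1e-12))
    expect_true(all(s >= 0 & s <= 1))
  }
})

test_that("ccd_fit methods: simulate round-trip, summary, lsq mode, bootstrap", {
  set.seed(50)
  f <- fit_ccd(rexp(2000, 1 / 15), "exp1")
  sim <- simulate(f, nsim = 2, seed = 3, n = 1000)
  expect_equal(dim(sim), c(1000, 2))
  refit <- fit_ccd(sim$sim_1, "exp1")
  expect_equal(unname(coef(refit)["tau"]), unname(coef(f)["tau"]),
               tolerance = 0.1)
  expect_output(print(summary(f)), "model exp1")
  flsq <- fit_ccd(f$data, "exp1", method = "lsq")
  expect_equal(unname(coef(flsq)["tau"]), unname(coef(f)["tau"]),
               tolerance = 0.15)
  bse <- boot_se(f, B = 60, seed = 4)
  expect_equal(unname(bse["tau"]), unname(f$se["tau"]), tolerance = 0.3)
})
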