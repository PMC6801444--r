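#' Extract the first passage time from a kinetic trace
#'
#' The FPT is the first time at which dz(t) reaches or drops below
#' \code{threshold} (adsorption is a decrease of dz), with linear
#' interpolation between the bracketing samples so the value is not biased by
#' the frame stride. A trace that never crosses is censored at its end time; a
#' trace starting at or below the threshold yields FPT = 0 with a
#' \code{start_below} flag.
#'
#' @param trace a \code{kinetic_trace}.
#' @param threshold crossing location in nm (default 1.5).
#' @return list with \code{value} (ns), \code{censored}, \code{start_below},
#'   \code{traj_id}.
#' @export
extract_fpt <- function(trace, threshold = 1.5) {
  ok <- !is.na(trace$dz)
  t <- trace$time[ok]; dz <- trace$dz[ok]
  if (length(t) < 2) stop("trace has fewer than 2 samples", call. = FALSE)
  if (dz[1] <= threshold)
    return(list(value = 0, censored = FALSE, start_below = TRUE,
                traj_id = trace$traj_id %||% NA))
  i <- which(dz <= threshold)
  if (length(i) == 0)
    return(list(value = t[length(t)], censored = TRUE, start_below = FALSE,
                traj_id = trace$traj_id %||% NA))
  i <- i[1]
  value <- if (dz[i] == threshold) t[i] else
    t[i - 1] + (dz[i - 1] - threshold) / (dz[i - 1] - dz[i]) *
      (t[i] - t[i - 1])
  list(value = value, censored = FALSE, start_below = FALSE,
       traj_id = trace$traj_id %||% NA)
}

#' First-passage-time samples from a set of traces
#' @param traces list of \code{kinetic_trace}.
#' @param threshold crossing location in nm.
#' @return data.frame with columns \code{value}, \code{censored},
#'   \code{start_below}, \code{traj_id}.
#' @export
fpt_samples <- function(traces, threshold = 1.5) {
  do.call(rbind, lapply(traces, function(tr)
    as.data.frame(extract_fpt(tr, threshold))))
}

#' Empirical complementary cumulative distribution of FPTs
#'
#' Product-limit (Kaplan--Meier) survival estimate honoring censored samples
#' (computed with \pkg{survival}); reduces to 1 - ECDF without censoring.
#'
#' @param samples data.frame from \code{\link{fpt_samples}} or a numeric
#'   vector of uncensored times.
#' @return object of class \code{ccd_curve}: \code{time}, \code{surv} step
#'   values, and \code{fn}, a right-continuous step interpolator.
#' @export
empirical_ccd <- function(samples) {
  s <- .as_fpt(samples)
  if (nrow(s) < 1) stop("need at least one FPT sample", call. = FALSE)
  if (all(s$censored)) {
    warning("all samples censored; survival is identically 1", call. = FALSE)
    fit <- list(time = max(s$value), surv = 1)
  } else {
    fit <- survival::survfit(
      survival::Surv(s$value, !s$censored) ~ 1, se.fit = FALSE)
  }
  fn <- stats::stepfun(fit$time, c(1, fit$surv), right = FALSE)
  structure(list(time = fit$time, surv = fit$surv, fn = fn,
                 n = nrow(s), n_events = sum(!s$censored)),
            class = "ccd_curve")
}

.as_fpt <- function(samples) {
  if (is.numeric(samples))
    samples <- data.frame(value = samples, censored = FALSE)
  stopifnot(all(c("value", "censored") %in% names(samples)))
  samples
}

# survival functions of the three CCD models
surv_exp1 <- function(t, tau) exp(-t / tau)
surv_exp2 <- function(t, weight_fast, tau_fast, tau_slow)
  weight_fast * exp(-t / tau_fast) + (1 - weight_fast) * exp(-t / tau_slow)
surv_gamma <- function(t, shape, scale)
  stats::pgamma(t, shape = shape, scale = scale, lower.tail = FALSE)

# negative log-likelihoods with censoring, natural parameters
.nll_exp1 <- function(tau, t, d) {
  if (tau <= 0) return(Inf)
  -(sum(d) * (-log(tau)) - sum(t) / tau)
}
.nll_exp2 <- function(par, t, d) {
  w <- par[1]; tf <- par[2]; ts <- par[3]
  if (w < 0 || w > 1 || tf <= 0 || ts <= 0) return(Inf)
  lw <- log(w); l1w <- log1p(-w)
  # events: log(w/tf e^{-t/tf} + (1-w)/ts e^{-t/ts}), pairwise log-sum-exp
  a <- lw - log(tf) - t / tf
  b <- l1w - log(ts) - t / ts
  ld <- pmax(a, b) + log1p(exp(-abs(a - b)))
  a2 <- lw - t / tf
  b2 <- l1w - t / ts
  ls <- pmax(a2, b2) + log1p(exp(-abs(a2 - b2)))
  -(sum(ld[d]) + sum(ls[!d]))
}
.nll_gamma <- function(par, t, d) {
  sh <- par[1]; sc <- par[2]
  if (sh <= 0 || sc <= 0) return(Inf)
  ll <- sum(stats::dgamma(t[d], shape = sh, scale = sc, log = TRUE))
  if (any(!d))
    ll <- ll + sum(stats::pgamma(t[!d], shape = sh, scale = sc,
                                 lower.tail = FALSE, log.p = TRUE))
  if (!is.finite(ll)) return(Inf)
  -ll
}

#' Fit a parametric model to the CCD of first-passage times
#'
#' Maximum-likelihood fit with censoring: uncensored samples contribute
#' density terms and censored samples survival terms. Models: single
#' exponential (\code{exp1}, closed-form MLE equal to total time over event
#' count), a normalized two-exponential mixture (\code{exp2}, parameters
#' weight_fast, tau_fast, tau_slow with weight_slow = 1 - weight_fast) and a
#' gamma distribution. The mixture is fitted by deterministic multistart
#' (quantile-based starting values for the two time scales) with
#' best-likelihood selection, and flagged degenerate when the two time
#' constants collapse. Standard errors come from the observed information
#' (numerical Hessian at the MLE); \code{\link{boot_se}} offers a bootstrap
#' alternative. A secondary least-squares-on-log-CCD criterion is available
#' via \code{method = "lsq"}.
#'
#' @param samples data.frame from \code{\link{fpt_samples}} or numeric vector
#'   of uncensored times.
#' @param model "exp1", "exp2" or "gamma".
#' @param init optional named starting values (natural parameters).
#' @param starts number of multistart points for exp2/gamma.
#' @param method "mle" (default) or "lsq".
#' @return object of class \code{ccd_fit} with \code{print}, \code{summary},
#'   \code{coef}, \code{vcov}, \code{logLik}, \code{predict},
#'   \code{simulate} and \code{plot} methods.
#' @export
fit_ccd <- function(samples, model = c("exp1", "exp2", "gamma"), init = NULL,
                    starts = 8, method = c("mle", "lsq")) {
  model <- match.arg(model)
  method <- match.arg(method)
  s <- .as_fpt(samples)
  t <- s$value; d <- !s$censored
  n_ev <- sum(d)
  need <- if (model == "exp2") 10 else 5
  if (n_ev < need)
    stop(sprintf("model %s needs at least %d uncensored samples", model,
                 need), call. = FALSE)

  if (method == "lsq") return(.fit_ccd_lsq(s, model, starts))

  degenerate <- FALSE
  if (model == "exp1") {
    tau <- sum(t) / n_ev
    par <- c(tau = tau)
    vcov <- matrix(tau^2 / n_ev, 1, 1, dimnames = list("tau", "tau"))
    ll <- -.nll_exp1(tau, t, d)
    converged <- TRUE
  } else if (model == "exp2") {
    te <- sort(t[d])
    tf0 <- mean(te[seq_len(max(2, floor(n_ev / 2)))])
    ts0 <- mean(te[te >= stats::quantile(te, 0.9)])
    if (ts0 <= tf0) ts0 <- 2 * tf0
    grid <- expand.grid(w = c(0.5, 0.7, 0.85, 0.95), jf = c(1, 0.6))
    starts_list <- lapply(seq_len(min(starts, nrow(grid))), function(i)
      c(grid$w[i], tf0 * grid$jf[i], ts0 / grid$jf[i]))
    if (!is.null(init))
      starts_list <- c(list(unname(init[c("weight_fast", "tau_fast",
                                          "tau_slow")])), starts_list)
    best <- NULL
    for (p0 in starts_list) {
      x0 <- c(stats::qlogis(min(max(p0[1], 1e-3), 1 - 1e-3)),
              log(p0[2]), log(p0[3]))
      o <- try(stats::optim(x0, function(x)
        .nll_exp2(c(stats::plogis(x[1]), exp(x[2]), exp(x[3])), t, d),
        method = "BFGS", control = list(maxit = 500)), silent = TRUE)
      if (!inherits(o, "try-error") &&
          (is.null(best) || o$value < best$value)) best <- o
    }
    if (is.null(best)) stop("exp2 fit failed to converge from any start",
                            call. = FALSE)
    w <- stats::plogis(best$par[1]); tf <- exp(best$par[2])
    ts <- exp(best$par[3])
    if (tf > ts) { tmp <- tf; tf <- ts; ts <- tmp; w <- 1 - w }
    if (abs(log(ts / tf)) < 0.1) {
      degenerate <- TRUE
      warning("exp2 time constants nearly equal; effectively exp1",
              call. = FALSE)
    }
    par <- c(weight_fast = unname(w), tau_fast = unname(tf),
             tau_slow = unname(ts))
    vcov <- .obs_vcov(function(p) .nll_exp2(p, t, d), par)
    ll <- -best$value
    converged <- best$convergence == 0
  } else {
    te <- t[d]
    m <- mean(te); v <- stats::var(te)
    p0 <- c(max(m^2 / v, 0.05), max(v / m, 1e-6))
    jit <- seq(0.5, 2, length.out = max(starts, 2))
    best <- NULL
    for (j in jit) {
      o <- try(stats::optim(log(p0 * c(j, 1 / j)), function(x)
        .nll_gamma(exp(x), t, d), method = "BFGS",
        control = list(maxit = 500)), silent = TRUE)
      if (!inherits(o, "try-error") &&
          (is.null(best) || o$value < best$value)) best <- o
    }
    if (is.null(best)) stop("gamma fit failed to converge", call. = FALSE)
    par <- c(shape = exp(best$par[1]), scale = exp(best$par[2]))
    vcov <- .obs_vcov(function(p) .nll_gamma(p, t, d), par)
    ll <- -best$value
    converged <- best$convergence == 0
  }

  structure(list(model = model, coefficients = par, vcov = vcov,
                 se = sqrt(pmax(diag(vcov), 0)), loglik = ll,
                 df = length(par), nobs = length(t), n_events = n_ev,
                 converged = converged, degenerate = degenerate,
                 method = method, data = s),
            class = "ccd_fit")
}

# observed-information covariance via numerical Hessian; NA on failure
.obs_vcov <- function(nll, par) {
  H <- try(pracma::hessian(nll, par), silent = TRUE)
  nm <- names(par)
  if (inherits(H, "try-error") || any(!is.finite(H)))
    return(matrix(NA_real_, length(par), length(par),
                  dimnames = list(nm, nm)))
  V <- try(solve(H), silent = TRUE)
  if (inherits(V, "try-error") || any(diag(V) < 0))
    return(matrix(NA_real_, length(par), length(par),
                  dimnames = list(nm, nm)))
  dimnames(V) <- list(nm, nm)
  V
}

# least squares of log model survival against the log Kaplan-Meier curve
.fit_ccd_lsq <- function(s, model, starts) {
  km <- empirical_ccd(s)
  keep <- km$surv > 0
  tt <- km$time[keep]; ls <- log(km$surv[keep])
  obj <- switch(model,
    exp1 = function(x) sum((log(surv_exp1(tt, exp(x))) - ls)^2),
    exp2 = function(x) sum((log(surv_exp2(tt, stats::plogis(x[1]),
                                          exp(x[2]), exp(x[3]))) - ls)^2),
    gamma = function(x) sum((log(surv_gamma(tt, exp(x[1]),
                                            exp(x[2]))) - ls)^2))
  te <- s$value[!s$censored]
  x0 <- switch(model,
    exp1 = log(mean(te)),
    exp2 = c(stats::qlogis(0.9), log(mean(te) * 0.8), log(mean(te) * 3)),
    gamma = c(0, log(mean(te))))
  o <- stats::optim(x0, obj, method = if (model == "exp1") "Brent" else
    "BFGS", lower = if (model == "exp1") -10 else -Inf,
    upper = if (model == "exp1") 15 else Inf)
  par <- switch(model,
    exp1 = c(tau = exp(o$par)),
    exp2 = { w <- stats::plogis(o$par[1]); tf <- exp(o$par[2])
             ts <- exp(o$par[3])
             if (tf > ts) { tmp <- tf; tf <- ts; ts <- tmp; w <- 1 - w }
             c(weight_fast = w, tau_fast = tf, tau_slow = ts) },
    gamma = c(shape = exp(o$par[1]), scale = exp(o$par[2])))
  structure(list(model = model, coefficients = par,
                 vcov = matrix(NA_real_, length(par), length(par)),
                 se = rep(NA_real_, length(par)), loglik = NA_real_,
                 df = length(par), nobs = nrow(s),
                 n_events = sum(!s$censored), converged = o$convergence == 0,
                 degenerate = FALSE, method = "lsq", data = s),
            class = "ccd_fit")
}

#' Bootstrap standard errors for a CCD fit
#' @param fit a \code{ccd_fit}.
#' @param B number of resamples.
#' @param seed integer seed.
#' @return named vector of bootstrap standard errors.
#' @export
boot_se <- function(fit, B = 500, seed = 1) {
  s <- fit$data
  with_seed(seed, {
    est <- replicate(B, {
      idx <- sample(nrow(s), replace = TRUE)
      f <- try(suppressWarnings(
        fit_ccd(s[idx, , drop = FALSE], fit$model)), silent = TRUE)
      if (inherits(f, "try-error")) rep(NA_real_, fit$df) else coef(f)
    })
  })
  apply(matrix(est, nrow = fit$df), 1, stats::sd, na.rm = TRUE) |>
    stats::setNames(names(fit$coefficients))
}

#' Model survival function of a fitted CCD
#' @param object a \code{ccd_fit}.
#' @param times evaluation times (ns); defaults to the fitted sample times.
#' @param ... unused.
#' @export
predict.ccd_fit <- function(object, times = NULL, ...) {
  times <- times %||% sort(object$data$value)
  p <- object$coefficients
  switch(object$model,
    exp1 = surv_exp1(times, p["tau"]),
    exp2 = surv_exp2(times, p["weight_fast"], p["tau_fast"], p["tau_slow"]),
    gamma = surv_gamma(times, p["shape"], p["scale"]))
}

#' Simulate first-passage times from a fitted CCD model
#' @param object a \code{ccd_fit}.
#' @param nsim number of replicate datasets.
#' @param seed integer seed.
#' @param n samples per replicate (defaults to the fitted sample size).
#' @param ... unused.
#' @export
simulate.ccd_fit <- function(object, nsim = 1, seed = 1, n = NULL, ...) {
  n <- n %||% object$nobs
  p <- object$coefficients
  with_seed(seed, {
    draws <- replicate(nsim, switch(object$model,
      exp1 = stats::rexp(n, rate = 1 / p["tau"]),
      exp2 = {
        fast <- stats::runif(n) < p["weight_fast"]
        ifelse(fast, stats::rexp(n, 1 / p["tau_fast"]),
               stats::rexp(n, 1 / p["tau_slow"]))
      },
      gamma = stats::rgamma(n, shape = p["shape"], scale = p["scale"])),
      simplify = FALSE)
  })
  as.data.frame(stats::setNames(draws, paste0("sim_", seq_len(nsim))))
}

#' @export
coef.ccd_fit <- function(object, ...) object$coefficients

#' @export
vcov.ccd_fit <- function(object, ...) object$vcov

#' @export
logLik.ccd_fit <- function(object, ...) {
  structure(object$loglik, df = object$df, nobs = object$nobs,
            class = "logLik")
}

#' @export
print.ccd_fit <- function(x, ...) {
  cat(sprintf("ccd_fit: model %s (%s), %d samples (%d events)%s\n",
              x$model, x$method, x$nobs, x$n_events,
              if (x$degenerate) " [degenerate mixture]" else ""))
  est <- x$coefficients
  for (i in seq_along(est))
    cat(sprintf("  %-12s %10.4f  (se %.4f)\n", names(est)[i], est[i],
                x$se[i]))
  if (is.finite(x$loglik))
    cat(sprintf("  logLik %.2f | AIC %.2f\n", x$loglik,
                stats::AIC(logLik(x))))
  invisible(x)
}

#' @export
summary.ccd_fit <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se)
  out <- list(model = object$model, table = tab, loglik = object$loglik,
              aic = if (is.finite(object$loglik))
                stats::AIC(logLik(object)) else NA_real_,
              n = object$nobs, n_events = object$n_events,
              degenerate = object$degenerate)
  class(out) <- "summary.ccd_fit"
  out
}

#' @export
print.summary.ccd_fit <- function(x, ...) {
  cat(sprintf("CCD fit, model %s (n = %d, events = %d)\n", x$model, x$n,
              x$n_events))
  print(round(x$table, 4))
  cat(sprintf("logLik %.2f, AIC %.2f\n", x$loglik, x$aic))
  invisible(x)
}

#' @export
plot.ccd_fit <- function(x, ...) {
  km <- empirical_ccd(x$data)
  tt <- seq(0, max(x$data$value), length.out = 200)
  graphics::plot(km$time, km$surv, log = "y", type = "s", xlab = "FPT (ns)",
                 ylab = "CCD", main = paste("CCD fit:", x$model), ...)
  graphics::lines(tt, pmax(predict(x, tt), 1e-12), col = 2, lwd = 2)
  invisible(x)
}
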