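#' Configuration for the overdamped Langevin trace generator
#'
#' @param dt integration step (ns).
#' @param total_time trace span (ns); must be an integer multiple of
#'   \code{dt}.
#' @param d_dz,d_theta diffusion coefficients of the two coordinates at the
#'   surface temperature (nm^2/ns, deg^2/ns); the inverse friction per
#'   coordinate in kBT units.
#' @param temperature Kelvin; the noise amplitude scales with
#'   \code{sqrt(temperature / surface temperature)}, so zero temperature
#'   switches the noise off.
#' @param seed integer; identical seeds reproduce identical traces
#'   bit-for-bit.
#' @param init list with \code{dz = c(mean, sd)} and optionally
#'   \code{theta = c(mean, sd)}; when theta is NULL the initial angle is drawn
#'   on the surface's valley at the initial dz.
#' @return an object of class \code{langevin_config}.
#' @export
langevin_config <- function(dt = 0.01, total_time = 200, d_dz = 0.01,
                            d_theta = 300, temperature = 303.15, seed = 1,
                            init = list(dz = c(2.3, 0.03), theta = NULL)) {
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  n_steps <- total_time / dt
  if (abs(n_steps - round(n_steps)) > 1e-9)
    stop("total_time must be an integer number of steps", call. = FALSE)
  structure(list(dt = dt, total_time = total_time, d_dz = d_dz,
                 d_theta = d_theta, temperature = temperature, seed = seed,
                 init = init, n_steps = as.integer(round(n_steps))),
            class = "langevin_config")
}

#' Simulate kinetic (dz, theta) traces on a reference surface
#'
#' Euler--Maruyama integration of overdamped Langevin dynamics on the 2D
#' surface, vectorized over trajectories. Theta is wrapped to [0, 360). A
#' non-finite force aborts the affected trajectory at that step with a
#' diagnostic flag (remaining samples NA) rather than truncating silently.
#'
#' @param surface a \code{ref_surface}.
#' @param config a \code{langevin_config}.
#' @param n_traj number of trajectories.
#' @return list of \code{kinetic_trace} objects, each with \code{time},
#'   \code{dz}, \code{theta} vectors and metadata (\code{seed}, \code{dt},
#'   \code{aborted}, \code{abort_step}).
#' @export
simulate_traces <- function(surface, config, n_traj = 25) {
  stopifnot(inherits(surface, "ref_surface"),
            inherits(config, "langevin_config"))
  n_steps <- config$n_steps
  dt <- config$dt
  noise_scale <- sqrt(max(config$temperature, 0) / surface$temperature)
  sd_dz <- sqrt(2 * config$d_dz * dt) * noise_scale
  sd_th <- sqrt(2 * config$d_theta * dt) * noise_scale

  with_seed(config$seed, {
    dz <- stats::rnorm(n_traj, config$init$dz[1], config$init$dz[2])
    if (is.null(config$init$theta)) {
      th <- if (!is.null(surface$knots_dz))
        .theta_star(surface, dz) + stats::rnorm(n_traj, 0, 10)
      else stats::runif(n_traj, 0, 360)
    } else {
      th <- stats::rnorm(n_traj, config$init$theta[1], config$init$theta[2])
    }
    th <- wrap_deg(th)

    DZ <- matrix(NA_real_, n_steps + 1L, n_traj)
    TH <- matrix(NA_real_, n_steps + 1L, n_traj)
    DZ[1, ] <- dz; TH[1, ] <- th
    active <- rep(TRUE, n_traj)
    abort_step <- rep(NA_integer_, n_traj)

    for (s in seq_len(n_steps)) {
      if (!any(active)) break
      f <- surface_force(surface, dz[active], th[active])
      bad <- !is.finite(f$f_dz) | !is.finite(f$f_theta)
      if (any(bad)) {
        idx <- which(active)[bad]
        abort_step[idx] <- s
        active[idx] <- FALSE
        warning("non-finite force; aborted trajectory ",
                paste(idx, collapse = ", "), " at step ", s, call. = FALSE)
        if (!any(active)) break
        f <- surface_force(surface, dz[active], th[active])
      }
      na <- sum(active)
      dz[active] <- dz[active] + config$d_dz * f$f_dz * dt +
        sd_dz * stats::rnorm(na)
      th[active] <- wrap_deg(th[active] + config$d_theta * f$f_theta * dt +
                               sd_th * stats::rnorm(na))
      DZ[s + 1L, active] <- dz[active]
      TH[s + 1L, active] <- th[active]
    }
  })

  time <- seq(0, by = dt, length.out = n_steps + 1L)
  lapply(seq_len(n_traj), function(j) {
    structure(list(time = time, dz = DZ[, j], theta = TH[, j],
                   traj_id = j, seed = config$seed, dt = dt,
                   aborted = !is.na(abort_step[j]),
                   abort_step = abort_step[j]),
              class = "kinetic_trace")
  })
}

#' @export
print.kinetic_trace <- function(x, ...) {
  cat(sprintf("kinetic_trace %s: %d samples over %.1f ns%s\n",
              x$traj_id %||% "", length(x$time), max(x$time),
              if (isTRUE(x$aborted)) sprintf(" (aborted at step %d)",
                                             x$abort_step) else ""))
  invisible(x)
}
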