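#' Reference free-energy surfaces over (dz, theta)
#'
#' Analytic 2D surfaces used as ground truth for the kinetic and umbrella
#' generators. Coordinates are the peptide--bilayer separation dz (nm) and the
#' helix rotation angle theta (degrees, periodic with period 360); energies are
#' in kBT at \code{temperature}. All presets add soft quadratic walls outside
#' \code{dz_range} so the surface is finite on dz in [0.8, 3.0] nm.
#'
#' Presets:
#' \describe{
#'   \item{barrier}{two basins (pre-adsorption at large dz, post-adsorption at
#'     small dz) joined by a valley \code{theta_star(dz)} that passes through
#'     the requested saddle location; a Gaussian ridge along dz is calibrated
#'     numerically so the minimum-over-paths maximum between the basins equals
#'     \code{saddle_height} exactly. Default rotation sense is the D
#'     enantiomer's (theta increasing as dz decreases).}
#'   \item{downhill}{a single funnel, monotone decreasing free energy along the
#'     adsorption path; default sense is the L enantiomer's.}
#'   \item{flat}{walls only; zero inside the dz range.}
#'   \item{harmonic}{1D harmonic well in dz (theta flat, no walls), for
#'     closed-form checks.}
#' }
#'
#' @param preset one of "barrier", "downhill", "flat", "harmonic".
#' @param chirality rotation sense of the adsorption path; defaults to "D" for
#'   the barrier preset and "L" for downhill.
#' @param saddle_height barrier height in kBT measured from the pre-adsorption
#'   basin (barrier preset).
#' @param saddle_dz,saddle_theta saddle location (nm, degrees in the D
#'   convention; mirrored internally for chirality "L").
#' @param temperature Kelvin.
#' @param angular_stiffness kBT prefactor of the 1 - cos(theta - theta_star)
#'   restraint that shapes the valley.
#' @param well_depth_pre,well_depth_post,well_sigma,ridge_sigma Gaussian well
#'   and ridge parameters of the barrier preset (kBT, nm).
#' @param downhill_depth funnel depth of the downhill preset (kBT).
#' @param harmonic_kappa,harmonic_center harmonic preset stiffness (kBT/nm^2)
#'   and center (nm).
#' @param dz_range soft wall positions (nm).
#' @param wall_k wall stiffness (kBT/nm^2).
#' @return an object of class \code{ref_surface}.
#' @export
ref_surface <- function(preset = c("barrier", "downhill", "flat", "harmonic"),
                        chirality = NULL,
                        saddle_height = 4.3, saddle_dz = 1.8,
                        saddle_theta = 150, temperature = 303.15,
                        angular_stiffness = 3,
                        well_depth_pre = 3, well_depth_post = 7,
                        well_sigma = 0.18, ridge_sigma = 0.10,
                        downhill_depth = 8,
                        harmonic_kappa = 10, harmonic_center = 1.75,
                        dz_range = c(1.0, 2.5), wall_k = 200) {
  preset <- match.arg(preset)
  chirality <- chirality %||%
    switch(preset, barrier = "D", downhill = "L", "L")

  p <- list(preset = preset, chirality = chirality,
            temperature = temperature, dz_range = dz_range, wall_k = wall_k,
            angular_stiffness = angular_stiffness)

  if (preset == "barrier") {
    d_pre <- 2.2; d_post <- 1.2
    # valley angles in the D convention; mirrored for an L-sense surface
    th_post <- 230; th_pre <- 90
    knots_dz <- c(d_post, saddle_dz, d_pre)
    knots_th <- c(th_post, saddle_theta, th_pre)
    if (chirality == "L") knots_th <- 360 - knots_th
    p <- c(p, list(d_pre = d_pre, d_post = d_post,
                   well_depth_pre = well_depth_pre,
                   well_depth_post = well_depth_post,
                   well_sigma = well_sigma, ridge_sigma = ridge_sigma,
                   saddle_dz = saddle_dz, saddle_height = saddle_height,
                   knots_dz = knots_dz, knots_th = knots_th))
    p$ridge_height <- .calibrate_ridge(p, saddle_height)
  } else if (preset == "downhill") {
    knots_dz <- c(1.2, 2.2)
    knots_th <- c(230, 90)               # D convention
    if (chirality == "L") knots_th <- 360 - knots_th
    p <- c(p, list(downhill_depth = downhill_depth, well_sigma = 0.4,
                   d_post = 1.2, knots_dz = knots_dz, knots_th = knots_th))
  } else if (preset == "harmonic") {
    p <- c(p, list(harmonic_kappa = harmonic_kappa,
                   harmonic_center = harmonic_center))
  }
  structure(p, class = "ref_surface")
}

# valley angle theta_star(dz): piecewise-linear through the knots, clamped
.theta_star <- function(p, dz) {
  stats::approx(p$knots_dz, p$knots_th, xout = pmin(pmax(dz, min(p$knots_dz)),
                                                    max(p$knots_dz)))$y
}

.wall <- function(p, dz) {
  lo <- p$dz_range[1]; hi <- p$dz_range[2]
  p$wall_k / 2 * (pmin(dz - lo, 0)^2 + pmax(dz - hi, 0)^2)
}

# 1D energy along the valley (barrier and downhill presets)
.valley_V <- function(p, dz) {
  if (p$preset == "barrier") {
    -p$well_depth_pre * exp(-(dz - p$d_pre)^2 / (2 * p$well_sigma^2)) -
      p$well_depth_post * exp(-(dz - p$d_post)^2 / (2 * p$well_sigma^2)) +
      p$ridge_height * exp(-(dz - p$saddle_dz)^2 / (2 * p$ridge_sigma^2)) +
      .wall(p, dz)
  } else {
    -p$downhill_depth * exp(-(dz - p$d_post)^2 / (2 * p$well_sigma^2)) +
      .wall(p, dz)
  }
}

.calibrate_ridge <- function(p, target) {
  grid <- seq(p$d_post, p$d_pre, length.out = 2001)
  barrier_of <- function(h) {
    p$ridge_height <- h
    v <- .valley_V(p, grid)
    i_max <- which.max(v)
    v[i_max] - min(v[grid >= grid[i_max]])
  }
  stats::uniroot(function(h) barrier_of(h) - target,
                 lower = 1e-3, upper = 50, tol = 1e-10)$root
}

#' Evaluate a reference surface (kBT)
#' @param surface a \code{ref_surface}.
#' @param dz,theta coordinates (recycled to common length).
#' @export
surface_energy <- function(surface, dz, theta) {
  p <- surface
  switch(p$preset,
    flat = .wall(p, dz) + 0 * theta,
    harmonic = p$harmonic_kappa / 2 * (dz - p$harmonic_center)^2 +
      0 * theta,
    {
      dth <- circ_diff_deg(theta, .theta_star(p, dz)) * pi / 180
      .valley_V(p, dz) + p$angular_stiffness * (1 - cos(dth))
    })
}

# numerical force (-gradient), central differences; theta component per degree
surface_force <- function(surface, dz, theta, h = 1e-4) {
  list(
    f_dz = -(surface_energy(surface, dz + h, theta) -
               surface_energy(surface, dz - h, theta)) / (2 * h),
    f_theta = -(surface_energy(surface, dz, theta + h) -
                  surface_energy(surface, dz, theta - h)) / (2 * h))
}

#' Analytic minimax barrier of a reference surface by dense grid search
#'
#' Evaluates the surface on a dense (dz, theta) grid and computes the
#' minimum-over-paths maximum energy between the two basins (theta-periodic,
#' 8-connected), independently of any sampled estimate.
#' @param surface a \code{ref_surface} (barrier or downhill preset).
#' @param n_dz,n_theta grid resolution.
#' @return list with \code{barrier} (kBT from the pre-adsorption basin),
#'   \code{saddle} (dz, theta) and the basin minima.
#' @export
surface_ref_barrier <- function(surface, n_dz = 301, n_theta = 181) {
  p <- surface
  if (!p$preset %in% c("barrier", "downhill"))
    stop("preset has no basins", call. = FALSE)
  dz <- seq(p$dz_range[1], p$dz_range[2], length.out = n_dz)
  th <- seq(0, 360, length.out = n_theta + 1)[1:n_theta]
  FF <- outer(dz, th, function(d, t) surface_energy(surface, d, t))
  pre_dz <- if (p$preset == "barrier") p$d_pre else max(p$knots_dz)
  post_dz <- p$d_post
  a <- .descend_to_min(FF, matrix(TRUE, n_dz, n_theta),
                       c(which.min(abs(dz - pre_dz)),
                         which.min(abs(th - .theta_star(p, pre_dz)))))
  b <- .descend_to_min(FF, matrix(TRUE, n_dz, n_theta),
                       c(which.min(abs(dz - post_dz)),
                         which.min(abs(th - .theta_star(p, post_dz)))))
  mp <- .minimax_path(FF, matrix(TRUE, n_dz, n_theta), a, b)
  list(barrier = mp$height - FF[a[1], a[2]],
       saddle = c(dz = dz[mp$saddle[1]], theta = th[mp$saddle[2]]),
       basin_pre = c(dz = dz[a[1]], theta = th[a[2]], F = FF[a[1], a[2]]),
       basin_post = c(dz = dz[b[1]], theta = th[b[2]], F = FF[b[1], b[2]]))
}

#' @export
print.ref_surface <- function(x, ...) {
  cat(sprintf("ref_surface: preset '%s' (%s sense), T = %.2f K\n",
              x$preset, x$chirality, x$temperature))
  if (x$preset == "barrier")
    cat(sprintf("  saddle %.2f kBT at dz = %.2f nm (calibrated ridge %.3f kBT)\n",
                x$saddle_height, x$saddle_dz, x$ridge_height))
  invisible(x)
}
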