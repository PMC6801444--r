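#' Sample harmonic umbrella windows on a reference surface
#'
#' Draws (dz, theta) samples from the biased density proportional to
#' exp(-[U(dz, theta) + k/2 (dz - c)^2] / kBT) in each window by Metropolis
#' random-walk Monte Carlo, vectorized over independent chains. The first
#' \code{burn_frac} of each chain (at least 200 steps) is discarded as
#' burn-in. By the convention used throughout, windows are indexed in order of
#' increasing center, so with the default 16 uniform centers on [1.0, 2.5] nm
#' window 16 sits at dz = 2.5 nm and window 8 at 1.7 nm.
#'
#' @param surface a \code{ref_surface}.
#' @param centers strictly increasing window centers (nm); default 16 uniform
#'   on [1.0, 2.5].
#' @param k_bias harmonic force constant in kJ/mol/nm^2.
#' @param n_samples minimum retained samples per window (post burn-in).
#' @param seed integer; same seed gives identical sample streams.
#' @param n_chains independent chains per window.
#' @param burn_frac burn-in fraction per chain.
#' @param prop_sd Metropolis proposal standard deviations c(dz nm, theta deg).
#' @return an object of class \code{umbrella_set}: per-window samples, the
#'   bias parameters, temperature, seed, acceptance rates and adjacent-window
#'   histogram overlaps.
#' @export
sample_umbrella <- function(surface, centers = seq(1.0, 2.5, length.out = 16),
                            k_bias = 1000, n_samples = 5000, seed = 1,
                            n_chains = 25, burn_frac = 0.1,
                            prop_sd = c(0.05, 15)) {
  stopifnot(inherits(surface, "ref_surface"))
  if (any(diff(centers) <= 0))
    stop("window centers must be strictly increasing", call. = FALSE)
  beta <- 1 / kBT_kJmol(surface$temperature)   # 1/(kJ/mol)
  kk <- beta * k_bias                          # kBT/nm^2
  sigma0 <- sqrt(1 / kk)

  keep <- ceiling(n_samples / n_chains)
  burn <- max(200L, ceiling(burn_frac * keep))

  windows <- vector("list", length(centers))
  with_seed(seed, {
    for (w in seq_along(centers)) {
      cc <- centers[w]
      dz <- cc + stats::rnorm(n_chains, 0, sigma0)
      th <- if (!is.null(surface$knots_dz))
        wrap_deg(.theta_star(surface, dz) + stats::rnorm(n_chains, 0, 15))
      else stats::runif(n_chains, 0, 360)
      e <- surface_energy(surface, dz, th) + kk / 2 * (dz - cc)^2
      SD <- matrix(NA_real_, keep, n_chains)
      ST <- matrix(NA_real_, keep, n_chains)
      acc <- 0L
      for (s in seq_len(burn + keep)) {
        dz_p <- dz + stats::rnorm(n_chains, 0, prop_sd[1])
        th_p <- wrap_deg(th + stats::rnorm(n_chains, 0, prop_sd[2]))
        e_p <- surface_energy(surface, dz_p, th_p) + kk / 2 * (dz_p - cc)^2
        ok <- log(stats::runif(n_chains)) < (e - e_p)
        dz[ok] <- dz_p[ok]; th[ok] <- th_p[ok]; e[ok] <- e_p[ok]
        if (s > burn) {
          SD[s - burn, ] <- dz
          ST[s - burn, ] <- th
          acc <- acc + sum(ok)
        }
      }
      windows[[w]] <- list(
        center = cc,
        samples = data.frame(dz = as.vector(SD), theta = as.vector(ST)),
        acceptance = acc / (keep * n_chains))
    }
  })

  out <- structure(list(windows = windows, centers = centers,
                        k_bias = k_bias, temperature = surface$temperature,
                        seed = seed, burn_in = burn, n_chains = n_chains,
                        bias_offset = rep(0, length(centers))),
                   class = "umbrella_set")
  out$overlap <- window_overlaps(out)
  if (length(out$overlap) && any(out$overlap <= 0.01))
    warning("adjacent umbrella windows with dz-histogram overlap <= 1%: ",
            paste(which(out$overlap <= 0.01), collapse = ", "),
            call. = FALSE)
  out
}

#' Histogram overlap between adjacent umbrella windows
#'
#' Overlap coefficient (sum of bin-wise minima of the normalized dz
#' histograms) for each adjacent window pair; a reweighting-quality
#' diagnostic.
#' @param uws an \code{umbrella_set}.
#' @param bin_width histogram bin width in nm.
#' @return numeric vector of length n_windows - 1.
#' @export
window_overlaps <- function(uws, bin_width = 0.01) {
  K <- length(uws$windows)
  if (K < 2) return(numeric(0))
  rng <- range(unlist(lapply(uws$windows, function(w) range(w$samples$dz))))
  breaks <- seq(rng[1] - bin_width, rng[2] + bin_width, by = bin_width)
  hmat <- vapply(uws$windows, function(w) {
    h <- graphics::hist(w$samples$dz, breaks = breaks, plot = FALSE)
    h$counts / sum(h$counts)
  }, numeric(length(breaks) - 1))
  vapply(seq_len(K - 1),
         function(i) sum(pmin(hmat[, i], hmat[, i + 1])), numeric(1))
}

#' @export
print.umbrella_set <- function(x, ...) {
  ns <- vapply(x$windows, function(w) nrow(w$samples), integer(1))
  cat(sprintf(
    "umbrella_set: %d windows on dz [%.2f, %.2f] nm, k = %g kJ/mol/nm^2\n",
    length(x$windows), min(x$centers), max(x$centers), x$k_bias))
  cat(sprintf("  %d samples/window; mean acceptance %.2f; min overlap %.3f\n",
              ns[1], mean(vapply(x$windows, `[[`, numeric(1), "acceptance")),
              if (length(x$overlap)) min(x$overlap) else NA_real_))
  invisible(x)
}
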