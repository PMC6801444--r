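#' Grid specification for the 2D PMF
#' @param dz_range dz limits in nm.
#' @param n_dz,n_theta bin counts along dz and theta (theta spans [0, 360)).
#' @export
pmf_grid <- function(dz_range = c(1.0, 2.5), n_dz = 30, n_theta = 36) {
  list(dz_edges = seq(dz_range[1], dz_range[2], length.out = n_dz + 1),
       theta_edges = seq(0, 360, length.out = n_theta + 1))
}

# statistical inefficiency of a series: 1 + 2 * sum of positive-lag acf
stat_ineff <- function(x, max_lag = 200) {
  if (length(x) < 10 || stats::sd(x) == 0) return(1)
  a <- stats::acf(x, lag.max = min(max_lag, length(x) - 1), plot = FALSE,
                  demean = TRUE)$acf[-1]
  neg <- which(a < 0)
  if (length(neg)) a <- a[seq_len(neg[1] - 1)]
  max(1, 1 + 2 * sum(a))
}

#' Estimate a 2D PMF over (dz, theta) from umbrella windows
#'
#' Solves the window free energies either by the self-consistent WHAM
#' iteration on a binned dz histogram or by the MBAR estimating equations on
#' the unbinned samples (both implemented here; convergence when the maximum
#' free-energy change between iterations falls below \code{tol} kBT). The
#' solved free energies give each sample an unbiased weight, and the 2D PMF
#' is obtained by binning the weighted samples over (dz, theta); a 1D profile
#' along dz is emitted alongside. Unsampled bins carry an explicit mask.
#' Samples are optionally subsampled by the statistical inefficiency of dz
#' before solving, keeping at least \code{min_keep} samples per window.
#'
#' @param uws an \code{umbrella_set}.
#' @param grid a \code{\link{pmf_grid}}.
#' @param estimator "mbar" (default) or "wham".
#' @param subsample logical; decorrelate by statistical inefficiency.
#' @param min_keep minimum retained samples per window when subsampling.
#' @param tol convergence tolerance on window free energies (kBT).
#' @param max_iter iteration cap.
#' @return object of class \code{pmf_surface}: free-energy matrix \code{F}
#'   (n_dz x n_theta, kBT, minimum over sampled bins = 0), \code{mask} of
#'   sampled bins, bin edges and midpoints, solved window free energies
#'   \code{f_windows}, the 1D profile \code{one_d}, and the weighted samples
#'   used (for reweighted expectations).
#' @export
estimate_pmf <- function(uws, grid = pmf_grid(),
                         estimator = c("mbar", "wham"), subsample = TRUE,
                         min_keep = 4000, tol = 1e-7, max_iter = 50000) {
  estimator <- match.arg(estimator)
  K <- length(uws$windows)
  if (K < 1) stop("no umbrella windows", call. = FALSE)
  beta <- 1 / kBT_kJmol(uws$temperature)
  kk <- beta * uws$k_bias                       # kBT / nm^2
  offs <- uws$bias_offset %||% rep(0, K)

  sub <- lapply(uws$windows, function(w) {
    s <- w$samples
    if (!all(is.finite(s$dz))) stop("non-finite dz sample", call. = FALSE)
    if (subsample) {
      g <- ceiling(stat_ineff(s$dz))
      g <- min(g, max(1, floor(nrow(s) / min_keep)))
      s <- s[seq(1, nrow(s), by = g), , drop = FALSE]
    }
    s
  })
  if (K > 1) {
    for (i in seq_len(K - 1)) {
      if (min(sub[[i + 1]]$dz) > max(sub[[i]]$dz))
        stop(sprintf("no dz overlap between windows %d and %d", i, i + 1),
             call. = FALSE)
    }
  }
  N_k <- vapply(sub, nrow, integer(1))
  dz_all <- unlist(lapply(sub, function(s) s$dz))
  th_all <- unlist(lapply(sub, function(s) s$theta))
  centers <- uws$centers

  # reduced bias energies of every sample in every window's potential
  u_fun <- function(dz) {
    vapply(seq_len(K),
           function(k) kk / 2 * (dz - centers[k])^2 + offs[k],
           numeric(length(dz)))                  # N x K
  }

  if (estimator == "mbar") {
    U <- u_fun(dz_all)                           # N x K
    lgN <- log(N_k)
    log_den_of <- function(f) {
      M <- sweep(-U, 2, lgN + f, FUN = "+")      # N x K: log N_l + f_l - u_l
      m <- do.call(pmax, as.data.frame(M))
      m + log(rowSums(exp(M - m)))               # length N
    }
    scf <- function(f) {
      A <- -U - log_den_of(f)                    # N x K
      a_max <- apply(A, 2, max)
      f_new <- -(a_max + log(colSums(exp(sweep(A, 2, a_max)))))
      f_new - f_new[1]
    }
    # minimize the convex multistate objective, then polish by
    # self-consistent iteration to the stated tolerance
    kappa <- function(fr) {
      f <- c(0, fr)
      sum(log_den_of(f)) - sum(N_k * f)
    }
    grad <- function(fr) {
      f <- c(0, fr)
      ld <- log_den_of(f)
      Ek <- colSums(exp(sweep(-U, 2, f, FUN = "+") - ld))
      (N_k * Ek - N_k)[-1]
    }
    f <- if (K == 1) 0 else
      c(0, stats::optim(rep(0, K - 1), kappa, grad, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-14))$par)
    delta <- Inf
    for (it in seq_len(max_iter)) {
      f_new <- scf(f)
      delta <- max(abs(f_new - f))
      f <- f_new
      if (delta < tol) break
    }
    if (delta >= tol)
      stop(sprintf("MBAR did not converge: residual %.2e after %d iterations",
                   delta, max_iter), call. = FALSE)
  } else {
    # WHAM on a fine dz histogram
    nb <- 200
    edges <- seq(min(dz_all) - 1e-9, max(dz_all) + 1e-9, length.out = nb + 1)
    mids <- (edges[-1] + edges[-(nb + 1)]) / 2
    H <- vapply(sub, function(s)
      tabulate(findInterval(s$dz, edges, rightmost.closed = TRUE), nb),
      numeric(nb))                               # nb x K
    n_b <- rowSums(H)
    Ub <- vapply(seq_len(K),
                 function(k) kk / 2 * (mids - centers[k])^2 + offs[k],
                 numeric(nb))                    # nb x K
    f <- rep(0, K)
    for (it in seq_len(max_iter)) {
      den <- as.vector(exp(sweep(-Ub, 2, f, FUN = "+")) %*% N_k)
      p_b <- n_b / pmax(den, 1e-300)
      fk <- -log(pmax(colSums(p_b * exp(-Ub)), 1e-300))
      fk <- fk - fk[1]
      delta <- max(abs(fk - f))
      f <- fk
      if (delta < tol) break
    }
    if (delta >= tol)
      stop(sprintf("WHAM did not converge: residual %.2e after %d iterations",
                   delta, max_iter), call. = FALSE)
    U <- u_fun(dz_all)
  }

  # unbiased per-sample log weights from the solved free energies
  M <- sweep(-U, 2, log(N_k) + f, FUN = "+")
  m <- do.call(pmax, as.data.frame(M))
  logw <- -(m + log(rowSums(exp(M - m))))
  logw <- logw - log_sum_exp(logw)

  n_dz <- length(grid$dz_edges) - 1
  n_th <- length(grid$theta_edges) - 1
  ib <- findInterval(dz_all, grid$dz_edges, rightmost.closed = TRUE)
  jb <- findInterval(wrap_deg(th_all), grid$theta_edges,
                     rightmost.closed = TRUE)
  inside <- ib >= 1 & ib <= n_dz & jb >= 1 & jb <= n_th
  Wsum <- matrix(0, n_dz, n_th)
  Nbin <- matrix(0L, n_dz, n_th)
  w_lin <- exp(logw)
  idx <- cbind(ib[inside], jb[inside])
  for (r in seq_len(nrow(idx))) {
    Wsum[idx[r, 1], idx[r, 2]] <- Wsum[idx[r, 1], idx[r, 2]] +
      w_lin[inside][r]
    Nbin[idx[r, 1], idx[r, 2]] <- Nbin[idx[r, 1], idx[r, 2]] + 1L
  }
  mask <- Nbin > 0
  FF <- matrix(NA_real_, n_dz, n_th)
  FF[mask] <- -log(Wsum[mask])
  FF <- FF - min(FF[mask])

  # 1D profile along dz
  w1 <- tapply(w_lin[inside], ib[inside], sum)
  one_d <- data.frame(
    dz = (grid$dz_edges[-1] + grid$dz_edges[-(n_dz + 1)])[
      as.integer(names(w1))] / 2,
    F = -log(as.numeric(w1)))
  one_d$F <- one_d$F - min(one_d$F)

  structure(list(F = FF, mask = mask, dz_edges = grid$dz_edges,
                 theta_edges = grid$theta_edges,
                 dz_mids = (grid$dz_edges[-1] +
                              grid$dz_edges[-(n_dz + 1)]) / 2,
                 theta_mids = (grid$theta_edges[-1] +
                                 grid$theta_edges[-(n_th + 1)]) / 2,
                 f_windows = f, estimator = estimator, one_d = one_d,
                 n_bin = Nbin, iterations = it,
                 samples = data.frame(dz = dz_all, theta = th_all,
                                      logw = logw),
                 temperature = uws$temperature),
            class = "pmf_surface")
}

#' Reweighted conditional expectation of an observable
#'
#' Unbiased expectation and standard deviation of an observable conditioned
#' on dz bins, using the solved window free energies of a PMF fit.
#'
#' @param uws the \code{umbrella_set} that produced \code{fit}.
#' @param observable function(dz, theta) -> numeric, evaluated on the
#'   weighted samples.
#' @param fit a \code{pmf_surface} from \code{\link{estimate_pmf}}; computed
#'   with defaults when NULL.
#' @param dz_edges conditioning bin edges (defaults to the fit's grid).
#' @return data.frame with one row per sampled bin: \code{dz}, \code{mean},
#'   \code{sd}, \code{n} and the effective sample size \code{n_eff}.
#' @export
reweighted_expectation <- function(uws, observable, fit = NULL,
                                   dz_edges = NULL) {
  fit <- fit %||% estimate_pmf(uws)
  dz_edges <- dz_edges %||% fit$dz_edges
  s <- fit$samples
  o <- observable(s$dz, s$theta)
  if (length(o) != nrow(s))
    stop("observable must return one value per sample", call. = FALSE)
  ib <- findInterval(s$dz, dz_edges, rightmost.closed = TRUE)
  nb <- length(dz_edges) - 1
  mids <- (dz_edges[-1] + dz_edges[-(nb + 1)]) / 2
  out <- do.call(rbind, lapply(seq_len(nb), function(b) {
    sel <- ib == b
    if (!any(sel)) return(NULL)
    w <- exp(s$logw[sel] - log_sum_exp(s$logw[sel]))
    mu <- sum(w * o[sel])
    v <- sum(w * (o[sel] - mu)^2)
    data.frame(dz = mids[b], mean = mu, sd = sqrt(max(v, 0)),
               n = sum(sel), n_eff = 1 / sum(w^2))
  }))
  out
}

# ---- minimax path machinery (theta-periodic, 8-connected) ----

# shift matrix M by (di, dj); rows (dz) pad with NA, cols (theta) wrap
.shift_mat <- function(M, di, dj) {
  n <- nrow(M); m <- ncol(M)
  out <- M
  if (dj != 0) out <- out[, ((seq_len(m) - 1 - dj) %% m) + 1, drop = FALSE]
  if (di > 0) out <- rbind(matrix(NA, di, m), out[seq_len(n - di), ,
                                                  drop = FALSE])
  if (di < 0) out <- rbind(out[(1 - di):n, , drop = FALSE],
                           matrix(NA, -di, m))
  out
}

.neigh_offsets <- expand.grid(di = -1:1, dj = -1:1)
.neigh_offsets <- .neigh_offsets[!(.neigh_offsets$di == 0 &
                                     .neigh_offsets$dj == 0), ]

# does `allowed` connect a to b? returns wavefront arrival steps or NULL
.flood <- function(allowed, a, b) {
  steps <- matrix(NA_integer_, nrow(allowed), ncol(allowed))
  if (!allowed[a[1], a[2]] || !allowed[b[1], b[2]]) return(NULL)
  steps[a[1], a[2]] <- 0L
  front <- !is.na(steps)
  it <- 0L
  repeat {
    it <- it + 1L
    grown <- front
    for (r in seq_len(nrow(.neigh_offsets))) {
      sh <- .shift_mat(front, .neigh_offsets$di[r], .neigh_offsets$dj[r])
      sh[is.na(sh)] <- FALSE
      grown <- grown | sh
    }
    grown <- grown & allowed
    new <- grown & !front
    if (!any(new)) break
    steps[new] <- it
    front <- grown
    if (front[b[1], b[2]]) break
  }
  if (is.na(steps[b[1], b[2]])) NULL else steps
}

# backtrack a path from b to a along decreasing wavefront steps
.backtrack <- function(steps, a, b) {
  n <- nrow(steps); m <- ncol(steps)
  path <- list(b)
  cur <- b
  while (!(cur[1] == a[1] && cur[2] == a[2])) {
    s_cur <- steps[cur[1], cur[2]]
    found <- FALSE
    for (r in seq_len(nrow(.neigh_offsets))) {
      i <- cur[1] + .neigh_offsets$di[r]
      j <- ((cur[2] - 1 + .neigh_offsets$dj[r]) %% m) + 1
      if (i >= 1 && i <= n && !is.na(steps[i, j]) &&
          steps[i, j] == s_cur - 1L) {
        cur <- c(i, j)
        path[[length(path) + 1]] <- cur
        found <- TRUE
        break
      }
    }
    if (!found) stop("backtrack failed", call. = FALSE)
  }
  do.call(rbind, rev(path))
}

# minimax path between bins a and b on matrix FF restricted to mask:
# smallest h such that a, b are connected within {F <= h}
.minimax_path <- function(FF, mask, a, b) {
  vals <- sort(unique(FF[mask & is.finite(FF)]))
  lo <- max(FF[a[1], a[2]], FF[b[1], b[2]])
  vals <- vals[vals >= lo]
  lo_i <- 1L; hi_i <- length(vals)
  if (is.null(.flood(mask & FF <= vals[hi_i], a, b)))
    stop("basins are disconnected through sampled bins", call. = FALSE)
  while (lo_i < hi_i) {
    mid <- (lo_i + hi_i) %/% 2L
    if (!is.null(.flood(mask & FF <= vals[mid], a, b))) hi_i <- mid
    else lo_i <- mid + 1L
  }
  h <- vals[lo_i]
  steps <- .flood(mask & FF <= h, a, b)
  path <- .backtrack(steps, a, b)
  on_path <- FF[path]
  sad <- path[which.max(on_path), ]
  list(height = max(on_path), saddle = sad, path = path)
}

# steepest descent to a local minimum over the 8-neighborhood
.descend_to_min <- function(FF, mask, start) {
  n <- nrow(FF); m <- ncol(FF)
  cur <- start
  repeat {
    best <- cur; bf <- FF[cur[1], cur[2]]
    for (r in seq_len(nrow(.neigh_offsets))) {
      i <- cur[1] + .neigh_offsets$di[r]
      j <- ((cur[2] - 1 + .neigh_offsets$dj[r]) %% m) + 1
      if (i >= 1 && i <= n && mask[i, j] && is.finite(FF[i, j]) &&
          FF[i, j] < bf) {
        best <- c(i, j); bf <- FF[i, j]
      }
    }
    if (all(best == cur)) return(cur)
    cur <- best
  }
}

#' Locate the adsorption barrier on a PMF surface
#'
#' Snaps each basin seed to the nearest sampled bin and descends to its local
#' minimum, then finds the minimax path between the two minima on the
#' 8-connected, theta-periodic bin graph (the path whose maximum free energy
#' is smallest, crossing sampled bins only). The saddle is the highest bin on
#' that path and the barrier is measured from the approach-side basin
#' (\code{basin_a}, the pre-adsorption basin).
#'
#' @param surface a \code{pmf_surface}.
#' @param basin_a pre-adsorption seed c(dz, theta).
#' @param basin_b post-adsorption seed c(dz, theta).
#' @return object of class \code{barrier_report}: basin and saddle locations
#'   with free energies, \code{barrier} (kBT), and the path as a data.frame.
#' @export
find_barrier <- function(surface, basin_a, basin_b) {
  snap <- function(seed) {
    i <- which.min(abs(surface$dz_mids - seed[1]))
    j <- which.min(circ_dist_deg(surface$theta_mids, seed[2]))
    if (!surface$mask[i, j]) {
      cand <- which(surface$mask, arr.ind = TRUE)
      dd <- (surface$dz_mids[cand[, 1]] - seed[1])^2 +
        (circ_dist_deg(surface$theta_mids[cand[, 2]], seed[2]) / 120)^2
      ij <- cand[which.min(dd), ]
      if (sum((surface$dz_mids[ij[1]] - seed[1])^2) > 0.04)
        stop("basin seed lies in an unsampled region", call. = FALSE)
      i <- ij[1]; j <- ij[2]
    }
    .descend_to_min(surface$F, surface$mask, c(i, j))
  }
  a <- snap(basin_a); b <- snap(basin_b)
  mp <- .minimax_path(surface$F, surface$mask, a, b)
  loc <- function(ij) c(dz = surface$dz_mids[ij[1]],
                        theta = surface$theta_mids[ij[2]],
                        F = surface$F[ij[1], ij[2]])
  structure(list(basin_pre = loc(a), basin_post = loc(b),
                 saddle = loc(mp$saddle),
                 barrier = mp$height - surface$F[a[1], a[2]],
                 path = data.frame(
                   dz = surface$dz_mids[mp$path[, 1]],
                   theta = surface$theta_mids[mp$path[, 2]],
                   F = surface$F[mp$path])),
            class = "barrier_report")
}

#' @export
print.pmf_surface <- function(x, ...) {
  cat(sprintf(
    "pmf_surface (%s): %d x %d bins over dz [%.2f, %.2f] nm x theta [0, 360)\n",
    x$estimator, nrow(x$F), ncol(x$F), min(x$dz_edges), max(x$dz_edges)))
  cat(sprintf("  sampled bins: %d/%d | converged in %d iterations\n",
              sum(x$mask), length(x$mask), x$iterations))
  invisible(x)
}

#' @export
plot.pmf_surface <- function(x, ...) {
  graphics::image(x$dz_mids, x$theta_mids, x$F, xlab = "dz (nm)",
                  ylab = expression(theta ~ (degree)),
                  main = sprintf("PMF (kBT, %s)", x$estimator), ...)
  graphics::contour(x$dz_mids, x$theta_mids, x$F, add = TRUE)
  invisible(x)
}

#' @export
print.barrier_report <- function(x, ...) {
  cat(sprintf(
    "barrier_report: %.2f kBT from pre basin (dz %.2f, theta %.0f)\n",
    x$barrier, x$basin_pre["dz"], x$basin_pre["theta"]))
  cat(sprintf("  saddle at dz = %.2f nm, theta = %.0f deg (F = %.2f kBT)\n",
              x$saddle["dz"], x$saddle["theta"], x$saddle["F"]))
  invisible(x)
}
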