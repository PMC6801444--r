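#' Pre/post-adsorption state policy
#'
#' Theta thresholds defining the two configuration classes, chirality
#' dependent and chirality symmetric (the L and D policies map onto each
#' other under theta -> 360 - theta): pre-adsorption is theta > 225 for L
#' (theta < 135 for D), post-adsorption theta < 180 for L (theta > 180 for
#' D). Inequalities are strict; boundary values and the gap in between are
#' "neither" and excluded from state averages.
#'
#' @param chirality "L" or "D".
#' @export
state_policy <- function(chirality = c("L", "D")) {
  chirality <- match.arg(chirality)
  structure(list(chirality = chirality), class = "state_policy")
}

#' Label a rotation angle as pre, post or neither
#' @param theta degrees in [0, 360); vectorized.
#' @param policy a \code{state_policy} (or "L"/"D").
#' @return character vector in \{"pre", "post", "neither"\}.
#' @export
label_state <- function(theta, policy) {
  if (is.character(policy)) policy <- state_policy(policy)
  theta <- wrap_deg(theta)
  if (policy$chirality == "L") {
    ifelse(theta > 225, "pre", ifelse(theta < 180, "post", "neither"))
  } else {
    ifelse(theta < 135, "pre", ifelse(theta > 180, "post", "neither"))
  }
}

#' Per-window state-conditioned observable summary with Welch tests
#'
#' For each umbrella window and state (pre/post), the mean of the observable,
#' its standard error of the mean (s/sqrt(n)) and the frame count; states
#' with fewer than 2 frames report the mean with a masked SEM. Welch
#' two-sample unequal-variance tests are run between the requested window
#' pairs within each state, reported at significance level \code{alpha}
#' without multiplicity correction (flagged in the metadata).
#'
#' @param uws an \code{umbrella_set}.
#' @param observable function(dz, theta) -> numeric, or a list of per-window
#'   numeric vectors aligned with the window samples.
#' @param policy a \code{state_policy} (or "L"/"D").
#' @param pairs list of integer window pairs to test (NULL for none).
#' @param alpha significance level (default 0.1).
#' @return object of class \code{window_stats}: \code{stats} data.frame
#'   (window, state, n, mean, sem) and \code{tests} data.frame (window_a,
#'   window_b, state, p_value, significant).
#' @export
window_state_summary <- function(uws, observable, policy, pairs = NULL,
                                 alpha = 0.1) {
  if (is.character(policy)) policy <- state_policy(policy)
  K <- length(uws$windows)
  vals <- vector("list", K)
  labs <- vector("list", K)
  for (w in seq_len(K)) {
    s <- uws$windows[[w]]$samples
    vals[[w]] <- if (is.function(observable))
      observable(s$dz, s$theta) else observable[[w]]
    if (length(vals[[w]]) != nrow(s))
      stop("observable length mismatch in window ", w, call. = FALSE)
    labs[[w]] <- label_state(s$theta, policy)
  }
  rows <- list()
  for (w in seq_len(K)) for (st in c("pre", "post")) {
    x <- vals[[w]][labs[[w]] == st]
    n <- length(x)
    rows[[length(rows) + 1]] <- data.frame(
      window = w, state = st, n = n,
      mean = if (n >= 1) mean(x) else NA_real_,
      sem = if (n >= 2) stats::sd(x) / sqrt(n) else NA_real_)
  }
  stats_df <- do.call(rbind, rows)
  tests <- NULL
  if (!is.null(pairs)) {
    tl <- list()
    for (pr in pairs) for (st in c("pre", "post")) {
      xa <- vals[[pr[1]]][labs[[pr[1]]] == st]
      xb <- vals[[pr[2]]][labs[[pr[2]]] == st]
      if (length(xa) >= 2 && length(xb) >= 2 &&
          (stats::sd(xa) > 0 || stats::sd(xb) > 0)) {
        p <- stats::t.test(xa, xb, var.equal = FALSE)$p.value
        tl[[length(tl) + 1]] <- data.frame(
          window_a = pr[1], window_b = pr[2], state = st, p_value = p,
          significant = p < alpha)
      }
    }
    tests <- if (length(tl)) do.call(rbind, tl) else NULL
  }
  structure(list(stats = stats_df, tests = tests, alpha = alpha,
                 multiplicity_correction = "none"),
            class = "window_stats")
}

#' @export
print.window_stats <- function(x, ...) {
  cat(sprintf("window_stats: %d (window, state) cells; alpha = %g (%s)\n",
              nrow(x$stats), x$alpha,
              paste("multiplicity correction:",
                    x$multiplicity_correction)))
  print(utils::head(x$stats, 8))
  invisible(x)
}

#' Assemble the analysis bundle
#'
#' Collects the upstream analyses into a single JSON + CSV bundle under
#' \code{out_dir}, stamped with the configuration hash and seeds. A pure
#' function of its inputs: rerunning with the same inputs writes
#' byte-identical tables.
#'
#' @param components named list with elements \code{ccd_fits} (named list of
#'   \code{ccd_fit}), \code{pmf} (\code{pmf_surface}), \code{barrier}
#'   (\code{barrier_report}), \code{window_stats} (\code{window_stats}),
#'   \code{tl_values} (numeric t.l samples), \code{switch_report}
#'   (\code{switch_report}). Any absent element triggers an error naming it.
#' @param out_dir output directory (created if needed).
#' @param config a \code{\link{default_run_config}}-shaped list.
#' @param seeds named list/vector of the seeds used upstream.
#' @param tl_bin_width histogram bin width for the t.l distribution.
#' @return invisibly, a list with the written paths and the config hash.
#' @export
assemble_report <- function(components, out_dir,
                            config = default_run_config(), seeds = list(),
                            tl_bin_width = 0.05) {
  required <- c("ccd_fits", "pmf", "barrier", "window_stats", "tl_values",
                "switch_report")
  absent <- setdiff(required, names(components))
  if (length(absent))
    stop("missing upstream artifacts: ", paste(absent, collapse = ", "),
         call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths[[name]] <<- p
  }

  fits <- components$ccd_fits
  fit_df <- do.call(rbind, lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    data.frame(fit = nm, model = f$model, parameter = names(coef(f)),
               estimate = unname(coef(f)), se = unname(f$se),
               aic = if (is.finite(f$loglik)) stats::AIC(logLik(f))
               else NA_real_)
  }))
  wr(fit_df, "ccd_fits.csv")

  pmf <- components$pmf
  grid_df <- expand.grid(dz = pmf$dz_mids, theta = pmf$theta_mids)
  grid_df$F_kBT <- as.vector(pmf$F)
  grid_df$sampled <- as.vector(pmf$mask)
  wr(grid_df, "pmf.csv")
  wr(pmf$one_d, "pmf_1d.csv")

  ws <- components$window_stats
  wr(ws$stats, "window_stats.csv")
  if (!is.null(ws$tests)) wr(ws$tests, "welch_tests.csv")

  tl <- components$tl_values
  breaks <- seq(-1, 1, by = tl_bin_width)
  h <- graphics::hist(pmin(pmax(tl, -1), 1), breaks = breaks, plot = FALSE)
  wr(data.frame(bin_mid = h$mids, count = h$counts), "tl_hist.csv")

  wr(components$switch_report$per_lipid, "switches.csv")

  br <- components$barrier
  summary <- list(
    config_hash = unname(hash),
    seeds = seeds,
    ccd_fits = lapply(fits, function(f)
      c(as.list(coef(f)), list(model = f$model,
                               degenerate = f$degenerate))),
    barrier = list(barrier_kBT = unname(br$barrier),
                   saddle_dz_nm = unname(br$saddle["dz"]),
                   saddle_theta_deg = unname(br$saddle["theta"])),
    pmf = list(estimator = pmf$estimator, n_sampled_bins = sum(pmf$mask)),
    switch_total = components$switch_report$n_switch,
    weights = as.list(config$contact$weights),
    tables = names(paths))
  jp <- file.path(out_dir, "report.json")
  jsonlite::write_json(summary, jp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths[["report.json"]] <- jp
  invisible(list(paths = paths, config_hash = hash))
}
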