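#' Pose a peptide above a bilayer at a given (dz, theta)
#'
#' Rotates the peptide about its own helix axis so its rotation angle equals
#' \code{theta}, then translates it so that the z distance between the
#' peptide and bilayer centers (unit masses over heavy atoms) equals
#' \code{dz}, laterally centered in the box.
#'
#' @param peptide a \code{peptide_model} with Trp (theta needs CG).
#' @param bilayer a \code{bilayer_model}.
#' @param dz target separation (nm).
#' @param theta target rotation angle (degrees).
#' @return the posed \code{peptide_model}.
#' @export
pose_peptide <- function(peptide, bilayer, dz, theta) {
  hf <- helix_axis(peptide_coords(peptide, "CA"))
  th0 <- rotation_angle(peptide, hf)
  peptide <- transform_peptide(peptide, axis = hf$axis,
                               angle_deg = circ_diff_deg(theta, th0),
                               origin = hf$centroid)
  pep_xyz <- peptide_coords(peptide)[peptide$atoms$heavy, , drop = FALSE]
  mem_xyz <- bilayer_coords(bilayer)
  target_xy <- if (!is.null(bilayer$box)) bilayer$box[1:2] / 2
  else colMeans(mem_xyz)[1:2]
  shift <- c(target_xy - colMeans(pep_xyz)[1:2],
             mean(mem_xyz[, 3]) + dz - mean(pep_xyz[, 3]))
  transform_peptide(peptide, translate = shift)
}

#' Run a small end-to-end synthetic analysis and write the report bundle
#'
#' Demonstration pipeline exercising every module on generated data: downhill
#' Langevin traces to first-passage times and CCD fits (exp1 and gamma);
#' barrier-preset umbrella sampling to a 2D PMF and a barrier report;
#' per-window rotation scores from peptide poses over a pseudo-bilayer,
#' summarized by state with Welch tests; a Trp-orientation sample; planted
#' side-hopping series counted into a switch report. All randomness derives
#' from \code{seed}; rerunning writes byte-identical tables.
#'
#' @param out_dir bundle output directory.
#' @param seed integer master seed.
#' @param n_traces kinetic trajectories for the FPT analysis.
#' @param n_samples umbrella samples per window.
#' @param frames_per_window poses scored per window.
#' @return invisibly, the \code{\link{assemble_report}} result.
#' @export
run_synthetic_report <- function(out_dir, seed = 1, n_traces = 6,
                                 n_samples = 1500, frames_per_window = 30) {
  config <- default_run_config()
  config$seed <- seed

  # kinetics: downhill traces -> FPT -> CCD fits
  sd_surface <- ref_surface("downhill")
  cfg <- langevin_config(total_time = 120, seed = seed)
  traces <- simulate_traces(sd_surface, cfg, n_traj = n_traces)
  fpt <- fpt_samples(traces, config$fpt_threshold)
  fits <- list(exp1 = fit_ccd(fpt, "exp1"),
               gamma = fit_ccd(fpt, "gamma"))

  # free energy: barrier-preset umbrella windows -> PMF -> barrier
  bar_surface <- ref_surface("barrier")
  uws <- sample_umbrella(bar_surface,
                         centers = seq(config$umbrella$dz_min,
                                       config$umbrella$dz_max,
                                       length.out = config$umbrella$n_windows),
                         k_bias = config$umbrella$k_bias,
                         n_samples = n_samples, seed = seed + 1)
  pmf <- estimate_pmf(uws, estimator = config$estimator)
  barrier <- find_barrier(pmf, basin_a = c(2.2, 90), basin_b = c(1.2, 230))

  # rotation scores from posed structures, per window and state
  pep <- build_peptide(C6_SEQUENCE, "D")
  mem <- build_bilayer(seed = seed)
  policy <- contact_policy(
    weights = unlist(config$contact$weights),
    scheme = config$contact$scheme, c2_class = config$contact$c2_class)
  uws_sub <- uws
  scores <- vector("list", length(uws$windows))
  for (w in seq_along(uws$windows)) {
    s <- uws$windows[[w]]$samples
    idx <- unique(round(seq(1, nrow(s), length.out = frames_per_window)))
    s <- s[idx, , drop = FALSE]
    uws_sub$windows[[w]]$samples <- s
    scores[[w]] <- vapply(seq_len(nrow(s)), function(i) {
      posed <- pose_peptide(pep, mem, s$dz[i], s$theta[i])
      contact_breakdown(posed, mem, policy)$S_rot
    }, numeric(1))
  }
  wstats <- window_state_summary(uws_sub, scores, state_policy("D"),
                                 pairs = list(c(8, 16)),
                                 alpha = config$states$alpha)

  # Trp orientation sample (mostly cis with a bad-orientation tail)
  tl_values <- with_seed(seed + 2, {
    ang <- c(stats::rnorm(160, 0, 25), stats::runif(40, 90, 270))
    vapply(ang, function(a)
      trp_orientation(build_peptide(C6_SEQUENCE, "D",
                                    indole_angle_deg = a))$dot,
      numeric(1))
  })

  # planted side-hopping series -> switch report
  sw <- with_seed(seed + 3, {
    series <- lapply(seq_len(20), function(l) {
      lab <- character(200)
      lab[1] <- sample(c("descending", "ascending"), 1)
      for (f in 2:200) {
        lab[f] <- if (stats::runif(1) < 0.02)
          setdiff(c("descending", "ascending"), lab[f - 1]) else lab[f - 1]
      }
      lab
    })
    names(series) <- seq_along(series)
    switch_events(series, debounce = config$contact$debounce)
  })

  assemble_report(
    list(ccd_fits = fits, pmf = pmf, barrier = barrier,
         window_stats = wstats, tl_values = tl_values, switch_report = sw),
    out_dir, config = config,
    seeds = list(main = seed, umbrella = seed + 1, tl = seed + 2,
                 switches = seed + 3),
    tl_bin_width = config$states$tl_bin_width)
}
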