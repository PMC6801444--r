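#' Default run configuration
#'
#' One declarative document collecting every tunable policy of the pipeline
#' with its default: contact cutoffs and weights, side-switch debounce,
#' Langevin and umbrella generator settings, the PMF grid and estimator, and
#' state/report options. Round-trips losslessly through YAML.
#' @export
default_run_config <- function() {
  list(
    contact = list(ambient_cutoff = 0.3, contact_cutoff = 0.5,
                   weights = list(w_dp = 1, w_dh = 1, w_ah = -1, w_ap = -1),
                   scheme = "lipid_atom", c2_class = "head", debounce = 5),
    langevin = list(dt = 0.01, total_time = 200, d_dz = 0.01, d_theta = 300,
                    temperature = 303.15),
    umbrella = list(dz_min = 1.0, dz_max = 2.5, n_windows = 16,
                    k_bias = 1000, n_samples = 5000, burn_frac = 0.1),
    grid = list(dz_min = 1.0, dz_max = 2.5, n_dz = 30, n_theta = 36),
    estimator = "mbar",
    fpt_threshold = 1.5,
    states = list(alpha = 0.1, tl_bin_width = 0.05),
    structure = list(lipid_resnames = c("POP", "POPC", "PSE"),
                     head_atoms = c("P", "N"), c2_atoms = "C2"),
    seed = 1)
}

#' Read / write a run configuration (YAML)
#' @param path file path.
#' @export
read_config <- function(path) yaml::read_yaml(path)

#' @rdname read_config
#' @param config a configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Hash of a configuration
#'
#' MD5 of the canonical JSON serialization; used to stamp report bundles.
#' @param config a configuration list.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

# ---- structures ----

#' Write peptide (and optionally bilayer) pseudo-structures as PDB
#'
#' Coordinates are converted from nm to Angstrom. Lipids are written with
#' residue name "POP", one residue per lipid, chain "M"; the peptide uses its
#' residue names on chain "A".
#'
#' @param peptide a \code{peptide_model} (or NULL).
#' @param path output path.
#' @param bilayer optional \code{bilayer_model}.
#' @export
write_structure_pdb <- function(peptide, path, bilayer = NULL) {
  xyz <- NULL; resno <- c(); resid <- c(); elety <- c(); chain <- c()
  if (!is.null(peptide)) {
    a <- peptide$atoms
    xyz <- rbind(xyz, as.matrix(a[, c("x", "y", "z")]))
    resno <- c(resno, a$res_id)
    resid <- c(resid, a$res_name)
    elety <- c(elety, a$atom)
    chain <- c(chain, rep("A", nrow(a)))
  }
  if (!is.null(bilayer)) {
    l <- bilayer$lipids
    xyz <- rbind(xyz, as.matrix(l[, c("x", "y", "z")]))
    resno <- c(resno, l$lipid_id)
    resid <- c(resid, rep("POP", nrow(l)))
    elety <- c(elety, l$atom)
    chain <- c(chain, rep("M", nrow(l)))
  }
  bio3d::write.pdb(file = path, xyz = as.vector(t(xyz * 10)),
                   resno = resno, resid = resid, elety = elety,
                   chain = chain)
  invisible(path)
}

#' Read a structure file into peptide and bilayer models
#'
#' Supports PDB (via \pkg{bio3d}) and GRO (minimal fixed-width reader).
#' Peptide residues are recognized by name (ARG/LEU/TRP); lipid residues by
#' \code{lipid_resnames}; any other residue name is an error listing the
#' offenders. Coordinates are normalized to nm. The peptide's helical-wheel
#' fragment assignment is recomputed from its sequence assuming the ideal
#' helix twist; a Trp lacking CD1/CH2 raises a warning and disables the
#' Trp-orientation statistics. A lipid without exactly one C2 atom is an
#' error.
#'
#' @param path file path.
#' @param format "pdb" or "gro" (default from the file extension).
#' @param chirality chirality tag to assign to the peptide model.
#' @param lipid_resnames residue names treated as lipids.
#' @param head_atoms,c2_atoms lipid atom names forming the head group and the
#'   chiral carbon; all other lipid atoms are tail.
#' @return list with \code{peptide} (\code{peptide_model} or NULL) and
#'   \code{bilayer} (\code{bilayer_model} or NULL).
#' @export
read_structure <- function(path, format = NULL, chirality = "L",
                           lipid_resnames = c("POP", "POPC", "PSE"),
                           head_atoms = c("P", "N"), c2_atoms = "C2") {
  format <- format %||% tolower(tools::file_ext(path))
  df <- switch(format,
    pdb = {
      p <- bio3d::read.pdb(path)
      a <- p$atom
      data.frame(resno = a$resno, resid = a$resid, atom = a$elety,
                 x = a$x / 10, y = a$y / 10, z = a$z / 10,
                 stringsAsFactors = FALSE)
    },
    gro = .read_gro(path),
    stop("unsupported structure format: ", format, call. = FALSE))

  pep_res <- c("ARG", "LEU", "TRP")
  is_pep <- df$resid %in% pep_res
  is_lip <- df$resid %in% lipid_resnames
  unknown <- unique(df$resid[!is_pep & !is_lip])
  if (length(unknown))
    stop("unknown residue name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)

  peptide <- NULL
  if (any(is_pep)) {
    pa <- df[is_pep, , drop = FALSE]
    resno <- pa$resno
    ids <- sort(unique(resno))
    res1 <- vapply(ids, function(i)
      names(.res3)[match(pa$resid[resno == i][1], .res3)], character(1))
    polarity <- ifelse(res1 == "R", "polar_charged", "nonpolar")
    trp <- which(res1 == "W")
    trp_index <- if (length(trp) == 1) trp else NA_integer_
    if (!is.na(trp_index)) {
      trp_atoms <- pa$atom[resno == ids[trp_index]]
      if (!all(c("CD1", "CH2") %in% trp_atoms))
        warning("Trp atoms CD1/CH2 missing; Trp statistics disabled",
                call. = FALSE)
    }
    atoms <- data.frame(
      res_id = match(resno, ids), res_name = pa$resid, atom = pa$atom,
      element = substr(pa$atom, 1, 1), x = pa$x, y = pa$y, z = pa$z,
      heavy = !startsWith(pa$atom, "H"), stringsAsFactors = FALSE)
    phi <- (seq_along(ids) - 1) * 100
    peptide <- structure(
      list(sequence = res1, chirality = chirality, atoms = atoms,
           polarity = polarity, trp_index = trp_index,
           fragments = assign_fragments(phi, polarity, 100),
           band_width = 100,
           helix = list(rise = 0.15, twist = 100, radius_ca = 0.23)),
      class = "peptide_model")
  }

  bilayer <- NULL
  if (any(is_lip)) {
    la <- df[is_lip, , drop = FALSE]
    ids <- unique(la$resno)
    role <- ifelse(la$atom %in% c2_atoms, "c2",
                   ifelse(la$atom %in% head_atoms, "head", "tail"))
    lipids <- data.frame(
      lipid_id = match(la$resno, ids), leaflet = NA_character_,
      role = role, atom = la$atom, element = substr(la$atom, 1, 1),
      x = la$x, y = la$y, z = la$z, heavy = !startsWith(la$atom, "H"),
      stringsAsFactors = FALSE)
    nc2 <- tapply(lipids$role == "c2", lipids$lipid_id, sum)
    bad <- names(nc2)[nc2 != 1]
    if (length(bad))
      stop("lipid(s) without exactly one C2 atom: ",
           paste(bad, collapse = ", "), call. = FALSE)
    mid <- stats::median(lipids$z)
    per <- tapply(lipids$z, lipids$lipid_id, mean)
    lipids$leaflet <- ifelse(per[as.character(lipids$lipid_id)] >= mid,
                             "upper", "lower")
    bilayer <- structure(
      list(lipids = lipids, box = NULL, normal_axis = "z",
           n_lipids = length(ids)),
      class = "bilayer_model")
  }
  list(peptide = peptide, bilayer = bilayer)
}

# minimal GRO reader (fixed-width, nm); returns the common structure frame
.read_gro <- function(path) {
  ln <- readLines(path)
  n <- as.integer(trimws(ln[2]))
  body <- ln[3:(2 + n)]
  data.frame(
    resno = as.integer(substr(body, 1, 5)),
    resid = trimws(substr(body, 6, 10)),
    atom = trimws(substr(body, 11, 15)),
    x = as.numeric(substr(body, 21, 28)),
    y = as.numeric(substr(body, 29, 36)),
    z = as.numeric(substr(body, 37, 44)),
    stringsAsFactors = FALSE)
}

#' Write a pseudo-structure in GRO format
#' @param peptide a \code{peptide_model} (or NULL).
#' @param path output path.
#' @param bilayer optional \code{bilayer_model}.
#' @export
write_structure_gro <- function(peptide, path, bilayer = NULL) {
  rows <- character(0)
  k <- 0L
  if (!is.null(peptide)) {
    a <- peptide$atoms
    for (i in seq_len(nrow(a))) {
      k <- k + 1L
      rows <- c(rows, sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                              a$res_id[i], a$res_name[i], a$atom[i], k,
                              a$x[i], a$y[i], a$z[i]))
    }
  }
  if (!is.null(bilayer)) {
    l <- bilayer$lipids
    off <- if (is.null(peptide)) 0L else max(peptide$atoms$res_id)
    for (i in seq_len(nrow(l))) {
      k <- k + 1L
      rows <- c(rows, sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                              l$lipid_id[i] + off, "POP", l$atom[i], k,
                              l$x[i], l$y[i], l$z[i]))
    }
  }
  box <- if (!is.null(bilayer) && !is.null(bilayer$box)) bilayer$box
  else c(10, 10, 10)
  writeLines(c("pseudo-structure", sprintf("%d", k), rows,
               sprintf("%10.5f%10.5f%10.5f", box[1], box[2], box[3])), path)
  invisible(path)
}

# ---- kinetic traces ----

#' Write kinetic traces as long-format CSV
#'
#' Columns: traj_id, time_ns, dz_nm, theta_deg.
#' @param traces list of \code{kinetic_trace}.
#' @param path output path.
#' @export
write_traces <- function(traces, path) {
  df <- do.call(rbind, lapply(traces, function(tr) {
    ok <- !is.na(tr$dz)
    data.frame(traj_id = tr$traj_id, time_ns = tr$time[ok],
               dz_nm = tr$dz[ok], theta_deg = tr$theta[ok])
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read kinetic traces from columnar text
#'
#' Accepts the long format written by \code{\link{write_traces}} or a single
#' trace with columns (time_ns, dz_nm, theta_deg). Time must be strictly
#' increasing within each trajectory; a duplicated or decreasing timestamp is
#' rejected with its row number.
#'
#' @param path CSV path.
#' @return list of \code{kinetic_trace}.
#' @export
read_traces <- function(path) {
  df <- utils::read.csv(path)
  need <- c("time_ns", "dz_nm", "theta_deg")
  if (!all(need %in% names(df)))
    stop("trace file must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!"traj_id" %in% names(df)) df$traj_id <- 1L
  lapply(split(seq_len(nrow(df)), df$traj_id), function(rows) {
    d <- df[rows, , drop = FALSE]
    bad <- which(diff(d$time_ns) <= 0)
    if (length(bad))
      stop("non-monotone time at row ", rows[bad[1] + 1], " of ", path,
           call. = FALSE)
    structure(list(time = d$time_ns, dz = d$dz_nm, theta = d$theta_deg,
                   traj_id = d$traj_id[1], seed = NA, dt = NA,
                   aborted = FALSE, abort_step = NA_integer_),
              class = "kinetic_trace")
  })
}

# ---- umbrella sets ----

#' Write an umbrella set as per-window CSVs plus a JSON manifest
#' @param uws an \code{umbrella_set}.
#' @param dir output directory.
#' @export
write_umbrella <- function(uws, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (w in seq_along(uws$windows))
    utils::write.csv(uws$windows[[w]]$samples,
                     file.path(dir, sprintf("window_%02d.csv", w)),
                     row.names = FALSE)
  jsonlite::write_json(
    list(centers = uws$centers, k_bias = uws$k_bias,
         temperature = uws$temperature, seed = uws$seed,
         burn_in = uws$burn_in, n_chains = uws$n_chains),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read an umbrella set written by \code{\link{write_umbrella}}
#' @param dir directory containing window CSVs and manifest.json.
#' @return an \code{umbrella_set}.
#' @export
read_umbrella <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  files <- sort(list.files(dir, pattern = "^window_\\d+\\.csv$",
                           full.names = TRUE))
  windows <- lapply(seq_along(files), function(w)
    list(center = man$centers[w], samples = utils::read.csv(files[w]),
         acceptance = NA_real_))
  out <- structure(list(windows = windows, centers = man$centers,
                        k_bias = man$k_bias, temperature = man$temperature,
                        seed = man$seed, burn_in = man$burn_in,
                        n_chains = man$n_chains,
                        bias_offset = rep(0, length(windows))),
                   class = "umbrella_set")
  out$overlap <- window_overlaps(out)
  out
}
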