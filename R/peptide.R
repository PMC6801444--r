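#' The C6 peptide sequence
#'
#' One-letter sequence of the 18-residue amphipathic helix C6
#' (Ac-RLLRLLLRLWRRLLRLLR-NH2), built from arginine, leucine and a single
#' tryptophan at position 10.
#' @export
C6_SEQUENCE <- "RLLRLLLRLWRRLLRLLR"

.res3 <- c(R = "ARG", L = "LEU", W = "TRP")

#' Build an ideal alpha-helical peptide model
#'
#' Constructs an idealized alpha-helix (rise 0.15 nm and twist 100 degrees per
#' residue) for a sequence over \{R, L, W\}, with pseudo side chains: a CB atom
#' for every residue and, for tryptophan, a rigid three-atom indole proxy
#' (CG, CD1, CH2) whose long axis CD1->CH2 has fixed length 0.55 nm. The helix
#' axis lies along +x, oriented from residue 1 to the last residue, so the
#' peptide starts parallel to a membrane whose normal is z.
#'
#' Nonpolar residues (Leu, Trp) are grouped into stacked surface fragments by
#' their helical-wheel angles: candidate links join nonpolar residues separated
#' by 1--4 positions whose circular wheel-angle distance is at most
#' \code{band_width}; links are accepted greedily by increasing angular
#' distance, each residue taking at most one predecessor and one successor, and
#' the resulting chains are the fragments. For C6 this yields four stacked
#' fragments with Trp on a longest one.
#'
#' A D-enantiomer is built by negating the y coordinate of the L model (a
#' mirror through the xz plane, which contains both the helix axis and the
#' membrane normal), leaving all intramolecular distances unchanged.
#'
#' @param sequence one-letter residue string using only R, L, W.
#' @param chirality "L" or "D".
#' @param band_width angular band (degrees) for fragment detection.
#' @param indole_angle_deg rotation of the indole long axis away from the local
#'   fragment tangent, about the outward radial direction at Trp; 0 places the
#'   indole cis (t.l ~ 1), 180 trans (t.l ~ -1).
#' @param rise,twist,radius_ca helix geometry (nm, degrees, nm).
#' @return an object of class \code{peptide_model}.
#' @export
build_peptide <- function(sequence, chirality = c("L", "D"),
                          band_width = 100, indole_angle_deg = 0,
                          rise = 0.15, twist = 100, radius_ca = 0.23) {
  chirality <- match.arg(chirality)
  res <- strsplit(sequence, "")[[1]]
  if (length(res) == 0) stop("empty sequence", call. = FALSE)
  bad <- setdiff(unique(res), names(.res3))
  if (length(bad))
    stop("unknown residue code(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  n <- length(res)
  polarity <- ifelse(res == "R", "polar_charged", "nonpolar")
  trp_index <- which(res == "W")
  if (length(trp_index) > 1)
    stop("model supports at most one Trp residue", call. = FALSE)
  if (length(trp_index) == 0) trp_index <- NA_integer_

  phi <- (seq_len(n) - 1) * twist          # helical-wheel angle, degrees
  x <- (seq_len(n) - 1) * rise
  radial <- cbind(0, cos(phi * pi / 180), sin(phi * pi / 180))

  rows <- list()
  add_atom <- function(i, atom, element, xyz) {
    rows[[length(rows) + 1L]] <<- data.frame(
      res_id = i, res_name = .res3[[res[i]]], atom = atom, element = element,
      x = xyz[1], y = xyz[2], z = xyz[3], stringsAsFactors = FALSE)
  }
  for (i in seq_len(n)) {
    add_atom(i, "CA", "C", c(x[i], radius_ca * radial[i, 2:3]))
    add_atom(i, "CB", "C", c(x[i], 0.33 * radial[i, 2:3]))
  }

  fragments <- assign_fragments(phi, polarity, band_width)

  if (!is.na(trp_index)) {
    i <- trp_index
    r_hat <- radial[i, ]
    cg <- c(x[i], 0.45 * radial[i, 2:3])
    add_atom(i, "CG", "C", cg)
    # indole long axis: fragment tangent (cis) rotated by indole_angle_deg
    # about the outward radial direction
    t_hat <- .fragment_tangent_ideal(fragments, trp_index, x, radial,
                                     radius_cb = 0.33)
    l_hat <- drop(rotate_about(matrix(t_hat, 1), r_hat, indole_angle_deg))
    mid <- cg + 0.12 * r_hat
    add_atom(i, "CD1", "C", mid - 0.275 * l_hat)
    add_atom(i, "CH2", "C", mid + 0.275 * l_hat)
  }

  atoms <- do.call(rbind, rows)
  atoms$heavy <- TRUE
  if (chirality == "D") atoms$y <- -atoms$y

  structure(list(sequence = res, chirality = chirality, atoms = atoms,
                 polarity = polarity, trp_index = trp_index,
                 fragments = fragments, band_width = band_width,
                 helix = list(rise = rise, twist = twist,
                              radius_ca = radius_ca)),
            class = "peptide_model")
}

# Greedy chain construction over nonpolar residues on the helical wheel.
# Returns an integer fragment id per residue (NA for polar residues).
assign_fragments <- function(phi, polarity, band_width) {
  n <- length(phi)
  frag <- rep(NA_integer_, n)
  np <- which(polarity == "nonpolar")
  if (length(np) == 0) return(frag)
  # candidate directed links i -> j, j the later residue
  cand <- list()
  for (a in seq_along(np)) {
    for (b in seq_along(np)) {
      i <- np[a]; j <- np[b]
      if (j > i && j - i <= 4) {
        d <- circ_dist_deg(phi[j], phi[i])
        if (d <= band_width)
          cand[[length(cand) + 1L]] <- c(i, j, d)
      }
    }
  }
  succ <- rep(NA_integer_, n)
  has_pred <- rep(FALSE, n)
  if (length(cand)) {
    cm <- do.call(rbind, cand)
    cm <- cm[order(cm[, 3], cm[, 2] - cm[, 1]), , drop = FALSE]
    for (r in seq_len(nrow(cm))) {
      i <- cm[r, 1]; j <- cm[r, 2]
      if (is.na(succ[i]) && !has_pred[j]) {
        succ[i] <- j
        has_pred[j] <- TRUE
      }
    }
  }
  fid <- 0L
  for (i in np) {
    if (!has_pred[i]) {          # chain head
      fid <- fid + 1L
      k <- i
      while (!is.na(k)) {
        frag[k] <- fid
        k <- succ[k]
      }
    }
  }
  frag
}

# Tangent of the Trp-containing fragment from ideal CB positions (quadratic
# fit over member rank; chord for two members; radial fallback for singletons).
.fragment_tangent_ideal <- function(fragments, trp_index, x, radial,
                                    radius_cb) {
  members <- which(!is.na(fragments) & fragments == fragments[trp_index])
  cb <- cbind(x[members], radius_cb * radial[members, 2, drop = FALSE],
              radius_cb * radial[members, 3, drop = FALSE])
  tangent_at(cb, which(members == trp_index))
}

# Tangent of an ordered point set at member position k: derivative of a
# per-coordinate quadratic fit in rank (chord if only two points).
tangent_at <- function(pts, k) {
  m <- nrow(pts)
  if (m < 2) stop("fragment with a single member has no tangent",
                  call. = FALSE)
  if (m == 2) return(unit_vec(pts[2, ] - pts[1, ]))
  s <- seq_len(m)
  d <- vapply(1:3, function(j) {
    fit <- stats::lm.fit(cbind(1, s, s^2), pts[, j])
    fit$coefficients[2] + 2 * fit$coefficients[3] * s[k]
  }, numeric(1))
  unit_vec(d)
}

#' Mirror a peptide model through the xz plane
#'
#' Negates the y coordinate of every atom and flips the chirality tag; the
#' mirror plane contains the helix axis (x) and the membrane normal (z), so the
#' enantiomer is returned in the same pose convention.
#' @param peptide a \code{peptide_model}.
#' @export
mirror_peptide <- function(peptide) {
  peptide$atoms$y <- -peptide$atoms$y
  peptide$chirality <- if (peptide$chirality == "L") "D" else "L"
  peptide
}

#' Coordinates of selected atoms as a matrix
#' @param peptide a \code{peptide_model}.
#' @param atoms optional atom-name filter (e.g. "CA").
#' @export
peptide_coords <- function(peptide, atoms = NULL) {
  a <- peptide$atoms
  if (!is.null(atoms)) a <- a[a$atom %in% atoms, , drop = FALSE]
  as.matrix(a[, c("x", "y", "z")])
}

#' Rigidly transform a peptide model
#'
#' @param peptide a \code{peptide_model}.
#' @param translate length-3 shift in nm.
#' @param axis,angle_deg,origin optional rotation (Rodrigues) applied before
#'   the translation.
#' @export
transform_peptide <- function(peptide, translate = c(0, 0, 0), axis = NULL,
                              angle_deg = 0, origin = c(0, 0, 0)) {
  xyz <- as.matrix(peptide$atoms[, c("x", "y", "z")])
  if (!is.null(axis) && angle_deg != 0)
    xyz <- rotate_about(xyz, axis, angle_deg, origin)
  xyz <- sweep(xyz, 2, translate, FUN = "+")
  peptide$atoms[, c("x", "y", "z")] <- xyz
  peptide
}

#' Rotate a peptide about its own helix axis in a chirality's adsorption sense
#'
#' The L enantiomer rotates with the rotation angle theta decreasing during
#' adsorption (clockwise about the oriented axis), the D enantiomer with theta
#' increasing. A positive \code{angle_deg} applies that sense.
#' @param peptide a \code{peptide_model}.
#' @param angle_deg rotation magnitude in degrees.
#' @param sense "L" or "D"; defaults to the model's chirality.
#' @export
rotate_in_sense <- function(peptide, angle_deg, sense = peptide$chirality) {
  hf <- helix_axis(peptide_coords(peptide, "CA"))
  sgn <- if (sense == "L") -1 else 1
  transform_peptide(peptide, axis = hf$axis, angle_deg = sgn * angle_deg,
                    origin = hf$centroid)
}

#' @export
print.peptide_model <- function(x, ...) {
  nfrag <- length(unique(stats::na.omit(x$fragments)))
  cat(sprintf("peptide_model: %d residues (%s), chirality %s\n",
              length(x$sequence), paste(x$sequence, collapse = ""),
              x$chirality))
  cat(sprintf("  Trp index: %s | nonpolar surface fragments: %d | atoms: %d\n",
              ifelse(is.na(x$trp_index), "none", x$trp_index), nfrag,
              nrow(x$atoms)))
  invisible(x)
}
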