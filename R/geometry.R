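#' Helix axis and centroid from ordered C-alpha coordinates
#'
#' The axis is the first principal direction of the centered C-alpha cloud,
#' with its sign chosen so that it points from the first toward the last
#' residue (axis . (CA_last - CA_first) > 0). If the top two singular values
#' are nearly equal the principal direction is ambiguous and the result
#' carries a warning flag.
#'
#' @param ca_coordinates n x 3 matrix of C-alpha positions (nm), in residue
#'   order; at least 4 points.
#' @return object of class \code{helix_frame}: \code{axis} (unit vector),
#'   \code{centroid}, \code{z_axis}, \code{ambiguous}.
#' @export
helix_axis <- function(ca_coordinates) {
  ca <- as.matrix(ca_coordinates)
  if (nrow(ca) < 4) stop("need at least 4 C-alpha points", call. = FALSE)
  centroid <- colMeans(ca)
  sv <- svd(sweep(ca, 2, centroid))
  axis <- sv$v[, 1]
  span <- ca[nrow(ca), ] - ca[1, ]
  if (sum(axis * span) < 0) axis <- -axis
  ambiguous <- (sv$d[1] - sv$d[2]) / sv$d[1] < 0.05
  if (ambiguous)
    warning("near-degenerate principal directions; helix axis ambiguous",
            call. = FALSE)
  structure(list(axis = axis, centroid = centroid, z_axis = c(0, 0, 1),
                 ambiguous = ambiguous),
            class = "helix_frame")
}

#' Helix rotation angle theta
#'
#' The signed dihedral about the oriented helix axis between the half-plane
#' containing +z and the half-plane containing the Trp CG atom, measured by
#' the right-hand rule and wrapped to [0, 360). Theta = 0 when CG lies
#' directly above the axis (toward +z), 180 when directly below.
#'
#' @param peptide a \code{peptide_model} with a Trp carrying atom CG.
#' @param helix optional precomputed \code{helix_frame}.
#' @return theta in degrees, in [0, 360).
#' @export
rotation_angle <- function(peptide, helix = NULL) {
  if (is.na(peptide$trp_index)) stop("peptide has no Trp", call. = FALSE)
  helix <- helix %||% helix_axis(peptide_coords(peptide, "CA"))
  a <- peptide$atoms
  cg <- a[a$res_id == peptide$trp_index & a$atom == "CG", c("x", "y", "z")]
  if (nrow(cg) != 1) stop("Trp atom CG not found", call. = FALSE)
  cg <- as.numeric(cg)
  u <- helix$axis
  za <- helix$z_axis - sum(helix$z_axis * u) * u
  if (sqrt(sum(za^2)) < 1e-9)
    stop("helix axis parallel to z; rotation angle undefined", call. = FALSE)
  b <- (cg - helix$centroid)
  b <- b - sum(b * u) * u
  if (sqrt(sum(b^2)) < 1e-9)
    stop("Trp CG lies on the helix axis; rotation angle undefined",
         call. = FALSE)
  wrap_deg(atan2(sum(u * cross3(za, b)), sum(za * b)) * 180 / pi)
}

#' Classify ambient lipids onto the descending or ascending side
#'
#' The vertical plane containing the helix axis and z splits space in two.
#' Under the chirality's rotation sense (L: theta decreasing; D: theta
#' increasing) one side of the helix cylinder moves downward (negative z
#' surface velocity); that side is the descending side. Each lipid is labeled
#' by the side of its chiral carbon C2 (or, optionally, its center of mass).
#' A lipid exactly in the dividing plane is assigned ascending and flagged.
#'
#' @param bilayer a \code{bilayer_model} (or fixture frame).
#' @param helix a \code{helix_frame}; its axis must be more than 1 degree away
#'   from vertical.
#' @param chirality "L" or "D".
#' @param lipid_ids optional subset of lipid ids (e.g. the ambient set).
#' @param basis "c2" (default) or "com".
#' @param tol in-plane tie tolerance (nm).
#' @return data.frame with \code{lipid_id}, \code{side} ("descending" or
#'   "ascending") and \code{tie} flag.
#' @export
classify_sides <- function(bilayer, helix, chirality = c("L", "D"),
                           lipid_ids = NULL, basis = c("c2", "com"),
                           tol = 1e-9) {
  chirality <- match.arg(chirality)
  basis <- match.arg(basis)
  u <- helix$axis
  if (acos(pmin(abs(u[3]), 1)) * 180 / pi < 1)
    stop("helix axis within 1 degree of vertical; sides undefined",
         call. = FALSE)
  n_hat <- unit_vec(cross3(u, helix$z_axis))
  # surface velocity at the +n side under the chirality's rotation sense
  omega <- (if (chirality == "L") -1 else 1) * u
  v_plus <- cross3(omega, n_hat)
  desc_sign <- if (v_plus[3] < 0) 1 else -1

  l <- bilayer$lipids
  if (!is.null(lipid_ids)) l <- l[l$lipid_id %in% lipid_ids, , drop = FALSE]
  ids <- unique(l$lipid_id)
  s <- vapply(ids, function(id) {
    li <- l[l$lipid_id == id, , drop = FALSE]
    p <- if (basis == "c2") {
      as.numeric(li[li$role == "c2", c("x", "y", "z")][1, ])
    } else {
      colMeans(as.matrix(li[, c("x", "y", "z")]))
    }
    sum((p - helix$centroid) * n_hat)
  }, numeric(1))
  tie <- abs(s) < tol
  side <- ifelse(!tie & (sign(s) == desc_sign), "descending", "ascending")
  data.frame(lipid_id = ids, side = side, tie = tie,
             stringsAsFactors = FALSE)
}

#' Trp indole orientation relative to the local helix groove
#'
#' Computes the dot product t . l where t is the unit tangent, at Trp, of the
#' surface fragment containing Trp (quadratic arc fit through the member CB
#' positions; chord for a two-member fragment) and l is the unit vector along
#' the indole long axis CD1 -> CH2. Values near 1 are cis ("well-orientated"),
#' near 0 perpendicular and near -1 trans ("bad-orientated").
#'
#' @param peptide a \code{peptide_model} with Trp in a fragment of >= 2
#'   members and atoms CD1/CH2 present.
#' @param helix unused placeholder for API symmetry; the statistic is frame
#'   independent.
#' @return object of class \code{trp_orientation}: \code{t}, \code{l},
#'   \code{dot}.
#' @export
trp_orientation <- function(peptide, helix = NULL) {
  if (is.na(peptide$trp_index)) stop("peptide has no Trp", call. = FALSE)
  fid <- peptide$fragments[peptide$trp_index]
  members <- which(!is.na(peptide$fragments) & peptide$fragments == fid)
  if (length(members) < 2)
    stop("Trp fragment has fewer than 2 members; tangent undefined",
         call. = FALSE)
  a <- peptide$atoms
  cb <- a[a$atom == "CB" & a$res_id %in% members, , drop = FALSE]
  cb <- cb[order(cb$res_id), , drop = FALSE]
  t_hat <- tangent_at(as.matrix(cb[, c("x", "y", "z")]),
                      which(cb$res_id == peptide$trp_index))
  cd1 <- a[a$res_id == peptide$trp_index & a$atom == "CD1", c("x", "y", "z")]
  ch2 <- a[a$res_id == peptide$trp_index & a$atom == "CH2", c("x", "y", "z")]
  if (nrow(cd1) != 1 || nrow(ch2) != 1)
    stop("Trp atoms CD1/CH2 missing", call. = FALSE)
  l_hat <- unit_vec(as.numeric(ch2) - as.numeric(cd1))
  structure(list(t = t_hat, l = l_hat, dot = sum(t_hat * l_hat)),
            class = "trp_orientation")
}

#' @export
print.trp_orientation <- function(x, ...) {
  cat(sprintf("trp_orientation: t.l = %.3f\n", x$dot))
  invisible(x)
}
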