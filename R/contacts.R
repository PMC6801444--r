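#' Contact-counting policy
#'
#' Cutoffs, contact weights and classification scheme used by the contact
#' statistics. Distances are between heavy atoms; with a periodic box the
#' minimum-image convention applies.
#'
#' The default weights (+1, +1, -1, -1) encode that contacts on the
#' descending side drive the rotation while contacts on the ascending side
#' impede it; they are configurable and every output records the weights
#' used.
#'
#' @param ambient_cutoff nm; a lipid is ambient when its nearest heavy atom is
#'   within this distance of the peptide (default 0.3 nm, i.e. 3 Angstrom).
#' @param contact_cutoff nm; a residue--lipid pair is in contact when any
#'   heavy-atom pair is within this distance (default 0.5 nm, i.e. 5
#'   Angstrom).
#' @param weights named vector (w_dp, w_dh, w_ah, w_ap) of Eq.-style contact
#'   weights for the rotation score.
#' @param scheme "lipid_atom" classifies each contact by the nearest
#'   contacting lipid atom (head -> polar, tail -> hydrophobic); "strict"
#'   counts only matched pairs: nonpolar residue with a tail atom
#'   (hydrophobic) and charged residue with a head atom (polar).
#' @param c2_class which partition the chiral carbon C2 belongs to for
#'   contact typing ("head" by default: it sits in the glycerol region).
#' @export
contact_policy <- function(ambient_cutoff = 0.3, contact_cutoff = 0.5,
                           weights = c(w_dp = 1, w_dh = 1,
                                       w_ah = -1, w_ap = -1),
                           scheme = c("lipid_atom", "strict"),
                           c2_class = c("head", "tail")) {
  scheme <- match.arg(scheme)
  c2_class <- match.arg(c2_class)
  stopifnot(ambient_cutoff > 0, contact_cutoff > 0,
            all(is.finite(weights)),
            all(c("w_dp", "w_dh", "w_ah", "w_ap") %in% names(weights)))
  structure(list(ambient_cutoff = ambient_cutoff,
                 contact_cutoff = contact_cutoff,
                 weights = weights[c("w_dp", "w_dh", "w_ah", "w_ap")],
                 scheme = scheme, c2_class = c2_class),
            class = "contact_policy")
}

# lipid-atom class under a policy: "head", "tail" (c2 mapped per policy)
.lipid_atom_class <- function(roles, policy) {
  ifelse(roles == "c2", policy$c2_class, roles)
}

#' Ambient-lipid filter
#'
#' Lipids whose minimum heavy-atom distance to any peptide heavy atom is at
#' most \code{ambient_cutoff}.
#'
#' @param peptide a \code{peptide_model}.
#' @param bilayer a \code{bilayer_model} (or fixture frame).
#' @param policy a \code{contact_policy}.
#' @return integer vector of ambient lipid ids (possibly empty).
#' @export
ambient_lipids <- function(peptide, bilayer, policy = contact_policy()) {
  l <- bilayer$lipids[bilayer$lipids$heavy, , drop = FALSE]
  if (nrow(l) == 0) return(integer(0))
  pep <- peptide_coords(peptide)[peptide$atoms$heavy, , drop = FALSE]
  d2 <- pair_dist2(as.matrix(l[, c("x", "y", "z")]), pep,
                   box = bilayer$box)
  dmin <- tapply(apply(d2, 1, min), l$lipid_id, min)
  as.integer(names(dmin)[dmin <= policy$ambient_cutoff^2])
}

#' Classified residue--lipid contact counts and the rotation score
#'
#' A (residue, lipid) pair contributes one contact when any heavy-atom pair
#' is within \code{contact_cutoff}. Each contact is classified into the four
#' classes \{descending, ascending\} x \{hydrophobic, polar\}: the side comes
#' from the lipid's side label, the interaction type from the classification
#' scheme of the policy. The rotation score is the weighted sum
#' S_rot = w_dp N_dp + w_dh N_dh + w_ah N_ah + w_ap N_ap.
#'
#' @param peptide a \code{peptide_model}.
#' @param bilayer a \code{bilayer_model}.
#' @param sides data.frame from \code{\link{classify_sides}} covering every
#'   counted lipid.
#' @param policy a \code{contact_policy}.
#' @param lipid_ids lipids to count (default: those in \code{sides}, i.e. the
#'   ambient set).
#' @return object of class \code{contact_breakdown}: counts \code{N_dp},
#'   \code{N_dh}, \code{N_ah}, \code{N_ap}, the score \code{S_rot} and the
#'   weights used.
#' @export
count_contacts <- function(peptide, bilayer, sides,
                           policy = contact_policy(),
                           lipid_ids = sides$lipid_id) {
  lab <- stats::setNames(sides$side, sides$lipid_id)
  if (!all(as.character(lipid_ids) %in% names(lab)))
    stop("side labels missing for some lipids", call. = FALSE)
  counts <- c(N_dp = 0L, N_dh = 0L, N_ah = 0L, N_ap = 0L)
  pa <- peptide$atoms[peptide$atoms$heavy, , drop = FALSE]
  cut2 <- policy$contact_cutoff^2
  for (id in lipid_ids) {
    li <- bilayer$lipids[bilayer$lipids$lipid_id == id &
                           bilayer$lipids$heavy, , drop = FALSE]
    if (!all(c("head", "tail") %in% li$role))
      stop("lipid ", id, " lacks a head/tail partition", call. = FALSE)
    lxyz <- as.matrix(li[, c("x", "y", "z")])
    lclass <- .lipid_atom_class(li$role, policy)
    d2 <- pair_dist2(as.matrix(pa[, c("x", "y", "z")]), lxyz,
                     box = bilayer$box)
    eta <- if (lab[[as.character(id)]] == "descending") "d" else "a"
    for (res in unique(pa$res_id)) {
      rows <- which(pa$res_id == res)
      dres <- d2[rows, , drop = FALSE]
      if (policy$scheme == "lipid_atom") {
        if (min(dres) > cut2) next
        xi <- if (lclass[which(dres == min(dres),
                               arr.ind = TRUE)[1, 2]] == "tail") "h" else "p"
      } else {
        pol <- peptide$polarity[res]
        want <- if (pol == "nonpolar") "tail" else "head"
        dsel <- dres[, lclass == want, drop = FALSE]
        if (length(dsel) == 0 || min(dsel) > cut2) next
        xi <- if (want == "tail") "h" else "p"
      }
      key <- paste0("N_", eta, xi)
      counts[key] <- counts[key] + 1L
    }
  }
  w <- policy$weights
  structure(list(N_dp = counts[["N_dp"]], N_dh = counts[["N_dh"]],
                 N_ah = counts[["N_ah"]], N_ap = counts[["N_ap"]],
                 S_rot = sum(w * counts[c("N_dp", "N_dh", "N_ah", "N_ap")]),
                 weights = w),
            class = "contact_breakdown")
}

#' @export
print.contact_breakdown <- function(x, ...) {
  cat(sprintf(
    "contact_breakdown: N_dp=%d N_dh=%d N_ah=%d N_ap=%d | S_rot = %.2f\n",
    x$N_dp, x$N_dh, x$N_ah, x$N_ap, x$S_rot))
  invisible(x)
}

#' Trp--head-group contact count
#'
#' Number of distinct lipids having at least one head atom within
#' \code{contact_cutoff} of any Trp heavy atom. A Trp--lipid pair forms at
#' most one contact, so the count equals the number of interacting lipids.
#'
#' @param peptide a \code{peptide_model} with a Trp.
#' @param bilayer a \code{bilayer_model} or fixture frame.
#' @param policy a \code{contact_policy}.
#' @param lipid_ids optional subset of lipids to consider.
#' @return integer count.
#' @export
trp_head_contacts <- function(peptide, bilayer, policy = contact_policy(),
                              lipid_ids = NULL) {
  if (is.na(peptide$trp_index)) stop("peptide has no Trp", call. = FALSE)
  trp <- peptide$atoms[peptide$atoms$res_id == peptide$trp_index &
                         peptide$atoms$heavy, , drop = FALSE]
  l <- bilayer$lipids[bilayer$lipids$heavy, , drop = FALSE]
  if (!is.null(lipid_ids)) l <- l[l$lipid_id %in% lipid_ids, , drop = FALSE]
  l <- l[.lipid_atom_class(l$role, policy) == "head", , drop = FALSE]
  if (nrow(l) == 0) return(0L)
  d2 <- pair_dist2(as.matrix(l[, c("x", "y", "z")]),
                   as.matrix(trp[, c("x", "y", "z")]), box = bilayer$box)
  length(unique(l$lipid_id[apply(d2, 1, min) <= policy$contact_cutoff^2]))
}

#' Descending/ascending lipid census
#'
#' Counts of ambient lipids on each side and their difference
#' delta_n = n_des - n_asc.
#'
#' @param sides data.frame from \code{\link{classify_sides}} restricted to
#'   the ambient set.
#' @return list with \code{n_des}, \code{n_asc}, \code{delta_n}.
#' @export
side_census <- function(sides) {
  n_des <- sum(sides$side == "descending")
  n_asc <- sum(sides$side == "ascending")
  list(n_des = n_des, n_asc = n_asc, delta_n = n_des - n_asc)
}

#' Full per-frame contact breakdown
#'
#' Convenience wrapper running the whole per-frame pipeline: ambient filter,
#' side classification, classified contact counts with the rotation score,
#' Trp--head contacts and the side census.
#'
#' @param peptide a \code{peptide_model}.
#' @param bilayer a \code{bilayer_model}.
#' @param policy a \code{contact_policy}.
#' @param chirality rotation-sense basis; defaults to the peptide's.
#' @param basis side-classification basis ("c2" or "com").
#' @return \code{contact_breakdown} extended with \code{trp_head_contacts},
#'   \code{n_des}, \code{n_asc}, \code{delta_n} and the ambient lipid ids.
#' @export
contact_breakdown <- function(peptide, bilayer, policy = contact_policy(),
                              chirality = peptide$chirality, basis = "c2") {
  amb <- ambient_lipids(peptide, bilayer, policy)
  helix <- helix_axis(peptide_coords(peptide, "CA"))
  if (length(amb) == 0) {
    sides <- data.frame(lipid_id = integer(0), side = character(0),
                        tie = logical(0))
    cb <- structure(list(N_dp = 0L, N_dh = 0L, N_ah = 0L, N_ap = 0L,
                         S_rot = 0, weights = policy$weights),
                    class = "contact_breakdown")
  } else {
    sides <- classify_sides(bilayer, helix, chirality, lipid_ids = amb,
                            basis = basis)
    cb <- count_contacts(peptide, bilayer, sides, policy)
  }
  cen <- side_census(sides)
  cb$trp_head_contacts <- if (!is.na(peptide$trp_index))
    trp_head_contacts(peptide, bilayer, policy) else NA_integer_
  cb$n_des <- cen$n_des; cb$n_asc <- cen$n_asc; cb$delta_n <- cen$delta_n
  cb$ambient <- amb
  cb
}

#' Count side-switch events in per-lipid label series
#'
#' A switch is a side-label change that persists for at least
#' \code{debounce} consecutive frames; shorter excursions are treated as
#' flicker and ignored. A lipid "experiences switching" when it has at least
#' one switch; the total is the number of such lipids.
#'
#' @param label_series named list (or frames x lipids matrix / data.frame) of
#'   per-lipid side-label sequences ("descending"/"ascending") on a common
#'   frame clock; all series must have equal length.
#' @param debounce minimum persistence in frames (default 5).
#' @return object of class \code{switch_report}: per-lipid switch counts and
#'   the total \code{n_switch}.
#' @export
switch_events <- function(label_series, debounce = 5) {
  if (is.matrix(label_series) || is.data.frame(label_series))
    label_series <- as.list(as.data.frame(label_series,
                                          stringsAsFactors = FALSE))
  len <- vapply(label_series, length, integer(1))
  if (length(unique(len)) != 1)
    stop("label series have mismatched frame counts", call. = FALSE)
  per <- vapply(label_series, function(s) {
    r <- rle(as.character(s))
    cur <- r$values[1]
    n <- 0L
    for (i in seq_along(r$values)[-1]) {
      if (r$lengths[i] >= debounce && r$values[i] != cur) {
        n <- n + 1L
        cur <- r$values[i]
      }
    }
    n
  }, integer(1))
  ids <- names(label_series) %||% as.character(seq_along(label_series))
  structure(list(per_lipid = data.frame(lipid_id = ids, n_switches = per,
                                        switched = per >= 1L,
                                        stringsAsFactors = FALSE),
                 n_switch = sum(per >= 1L), debounce = debounce),
            class = "switch_report")
}

#' Difference in switching-lipid totals between two systems
#' @param report_a,report_b \code{switch_report} objects (e.g. L and D).
#' @return \code{n_switch(report_a) - n_switch(report_b)}.
#' @export
switch_diff <- function(report_a, report_b) {
  report_a$n_switch - report_b$n_switch
}

#' @export
print.switch_report <- function(x, ...) {
  cat(sprintf(
    "switch_report: %d of %d lipids switch sides (debounce %d frames)\n",
    x$n_switch, nrow(x$per_lipid), x$debounce))
  invisible(x)
}
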