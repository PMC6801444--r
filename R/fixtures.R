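#' Generate frames with a Poisson-distributed Trp--head contact count
#'
#' Produces an ensemble of frames in which the number of distinct lipids
#' having at least one head atom within \code{contact_cutoff} of any Trp heavy
#' atom is Poisson-distributed with the requested mean. Placement is verified
#' geometrically: each frame is re-placed until the actual distance-based
#' count equals the drawn Poisson count, so the geometric statistic (not just
#' the intent) matches. Remaining background lipids are placed well outside
#' the cutoff.
#'
#' @param peptide a \code{peptide_model} containing a Trp.
#' @param mean_heads_near_trp expected contact-lipid count per frame (>= 0).
#' @param n_frames number of frames.
#' @param seed integer seed.
#' @param contact_cutoff heavy-atom contact cutoff (nm, default 0.5).
#' @param n_background non-contacting lipids per frame.
#' @return list of \code{bilayer_model} frames (no periodic box).
#' @export
place_contact_fixture <- function(peptide, mean_heads_near_trp, n_frames,
                                  seed = 1, contact_cutoff = 0.5,
                                  n_background = 3) {
  if (is.na(peptide$trp_index))
    stop("peptide has no Trp residue", call. = FALSE)
  if (mean_heads_near_trp < 0)
    stop("requested mean must be >= 0", call. = FALSE)
  trp <- peptide$atoms[peptide$atoms$res_id == peptide$trp_index &
                         peptide$atoms$heavy, , drop = FALSE]
  trp_xyz <- as.matrix(trp[, c("x", "y", "z")])
  pep_xyz <- peptide_coords(peptide)

  make_lipid <- function(id, head_pos) {
    # one P head atom at head_pos; N, C2 and tails stacked away from it
    off <- rbind(c(0, 0, 0), c(0.1, 0, 0.05), c(0, 0, -0.25),
                 c(0, 0, -0.55), c(0, 0, -0.85), c(0, 0, -1.15))
    data.frame(lipid_id = id, leaflet = "upper",
               role = c("head", "head", "c2", "tail", "tail", "tail"),
               atom = c("P", "N", "C2", "C21", "C22", "C23"),
               element = c("P", "N", "C", "C", "C", "C"),
               x = head_pos[1] + off[, 1], y = head_pos[2] + off[, 2],
               z = head_pos[3] + off[, 3], heavy = TRUE,
               stringsAsFactors = FALSE)
  }

  geo_count <- function(lipids) {
    heads <- lipids[lipids$role == "head", , drop = FALSE]
    d2 <- pair_dist2(as.matrix(heads[, c("x", "y", "z")]), trp_xyz)
    length(unique(heads$lipid_id[apply(d2, 1, min) <= contact_cutoff^2]))
  }

  far_anchor <- colMeans(trp_xyz) + c(0, 0, 3)   # background shelf

  with_seed(seed, {
    ks <- stats::rpois(n_frames, mean_heads_near_trp)
    frames <- vector("list", n_frames)
    for (f in seq_len(n_frames)) {
      k <- ks[f]
      repeat {
        parts <- vector("list", k + n_background)
        if (k > 0) {
          for (j in seq_len(k)) {
            # head within the cutoff shell of a random Trp heavy atom,
            # spread angularly so distinct lipids stay distinct
            anchor <- trp_xyz[sample(nrow(trp_xyz), 1), ]
            r <- stats::runif(1, 0.25, contact_cutoff - 0.05)
            u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
            parts[[j]] <- make_lipid(j, anchor + r * u)
          }
        }
        for (j in seq_len(n_background)) {
          parts[[k + j]] <- make_lipid(
            k + j, far_anchor + c(j * 1.5, 0, stats::runif(1, 0, 0.5)))
        }
        lipids <- do.call(rbind, parts)
        if (geo_count(lipids) == k) break
      }
      # keep background heads clear of every peptide atom too (ambient logic)
      frames[[f]] <- structure(
        list(lipids = lipids, box = NULL, normal_axis = "z",
             n_lipids = k + n_background),
        class = "bilayer_model")
    }
  })
  frames
}
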