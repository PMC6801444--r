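#' Build a coarse pseudo-POPC bilayer
#'
#' Places \code{n_lipids} pseudo-lipids on a jittered square lattice, half per
#' leaflet, with the membrane midplane at z = 0 and the membrane normal along
#' z. Each lipid carries two head atoms (phosphate and choline proxies), one
#' chiral-carbon atom C2 located between head and tail along z, and three tail
#' atoms, so head/tail partitions and the C2-based side classification behave
#' as for a real lipid. The lateral box area is \code{n_lipids/2 *
#' area_per_lipid}.
#'
#' @param n_lipids even lipid count (default 128, i.e. 64 per leaflet).
#' @param area_per_lipid lateral area per lipid in nm^2.
#' @param seed integer seed; identical seeds give identical coordinates.
#' @param jitter lateral jitter amplitude as a fraction of the lattice spacing.
#' @return an object of class \code{bilayer_model}.
#' @export
build_bilayer <- function(n_lipids = 128, area_per_lipid = 0.68, seed = 1,
                          jitter = 0.15) {
  if (n_lipids < 2 || n_lipids %% 2 != 0)
    stop("n_lipids must be even and >= 2", call. = FALSE)
  n_leaf <- n_lipids / 2
  nx <- ceiling(sqrt(n_leaf))
  ny <- ceiling(n_leaf / nx)
  spacing <- sqrt(area_per_lipid)
  box <- c(nx * spacing, ny * spacing, 12)

  # per-lipid z offsets (nm from midplane), upper leaflet; lower is mirrored
  zoff <- c(P = 1.95, N = 2.15, C2 = 1.65, C21 = 1.2, C22 = 0.8, C23 = 0.4)
  role <- c(P = "head", N = "head", C2 = "c2",
            C21 = "tail", C22 = "tail", C23 = "tail")
  elem <- c(P = "P", N = "N", C2 = "C", C21 = "C", C22 = "C", C23 = "C")

  with_seed(seed, {
    rows <- vector("list", n_lipids)
    for (l in seq_len(n_lipids)) {
      leaflet <- if (l <= n_leaf) "upper" else "lower"
      idx <- if (l <= n_leaf) l - 1L else l - n_leaf - 1L
      gx <- (idx %% nx + 0.5) * spacing
      gy <- (idx %/% nx + 0.5) * spacing
      gx <- gx + stats::runif(1, -jitter, jitter) * spacing
      gy <- gy + stats::runif(1, -jitter, jitter) * spacing
      sgn <- if (leaflet == "upper") 1 else -1
      rows[[l]] <- data.frame(
        lipid_id = l, leaflet = leaflet, role = unname(role),
        atom = names(zoff), element = unname(elem),
        x = gx + c(0, 0.05, 0.08, stats::runif(3, -0.05, 0.05)),
        y = gy + c(0, -0.05, 0.02, stats::runif(3, -0.05, 0.05)),
        z = sgn * unname(zoff),
        stringsAsFactors = FALSE)
    }
    lipids <- do.call(rbind, rows)
  })
  lipids$heavy <- TRUE

  structure(list(lipids = lipids, box = box, normal_axis = "z",
                 n_lipids = n_lipids, area_per_lipid = area_per_lipid,
                 seed = seed),
            class = "bilayer_model")
}

#' Mirror a bilayer model through the xz plane
#' @param bilayer a \code{bilayer_model}.
#' @export
mirror_bilayer <- function(bilayer) {
  bilayer$lipids$y <- -bilayer$lipids$y
  bilayer
}

#' Coordinates of selected lipid atoms as a matrix
#' @param bilayer a \code{bilayer_model}.
#' @param roles optional role filter ("head", "c2", "tail").
#' @export
bilayer_coords <- function(bilayer, roles = NULL) {
  l <- bilayer$lipids
  if (!is.null(roles)) l <- l[l$role %in% roles, , drop = FALSE]
  as.matrix(l[, c("x", "y", "z")])
}

#' @export
print.bilayer_model <- function(x, ...) {
  cat(sprintf(
    "bilayer_model: %d pseudo-lipids (%d per leaflet), box %.2f x %.2f x %.1f nm\n",
    x$n_lipids, x$n_lipids / 2, x$box[1], x$box[2], x$box[3]))
  invisible(x)
}

#' Validate a bilayer model's per-lipid structure
#'
#' Checks that every lipid has at least one head atom, at least one tail atom
#' and exactly one C2 atom, with C2 between head and tail along the membrane
#' normal within its leaflet.
#' @param bilayer a \code{bilayer_model}.
#' @return TRUE invisibly; otherwise an error naming the offending lipid.
#' @export
validate_bilayer <- function(bilayer) {
  for (l in split(bilayer$lipids, bilayer$lipids$lipid_id)) {
    nh <- sum(l$role == "head"); nt <- sum(l$role == "tail")
    nc <- sum(l$role == "c2")
    if (nh < 1 || nt < 1 || nc != 1)
      stop("lipid ", l$lipid_id[1], " lacks the head/C2/tail partition",
           call. = FALSE)
    zh <- abs(l$z[l$role == "head"]); zt <- abs(l$z[l$role == "tail"])
    zc <- abs(l$z[l$role == "c2"])
    if (!(zc < max(zh) && zc > min(zt)))
      stop("lipid ", l$lipid_id[1], ": C2 not between head and tail along z",
           call. = FALSE)
  }
  invisible(TRUE)
}
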