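# Shared fixtures and independent brute-force oracles. The oracles are
# written as plain loops from first principles so they stay independent of
# the vectorized implementation paths they check.

# a minimal pseudo-lipid: one P + one N head atom, one C2, two tail atoms
lipid_at <- function(id, head, c2 = head + c(0, 0, -0.3),
                     tail = head + c(0, 0, -0.7)) {
  data.frame(
    lipid_id = id, leaflet = "upper",
    role = c("head", "head", "c2", "tail", "tail"),
    atom = c("P", "N", "C2", "C21", "C22"),
    element = c("P", "N", "C", "C", "C"),
    x = c(head[1], head[1] + 0.08, c2[1], tail[1], tail[1] + 0.05),
    y = c(head[2], head[2] - 0.04, c2[2], tail[2], tail[2] + 0.05),
    z = c(head[3], head[3] + 0.05, c2[3], tail[3], tail[3] - 0.2),
    heavy = TRUE, stringsAsFactors = FALSE)
}

frame_of <- function(..., box = NULL) {
  structure(list(lipids = do.call(rbind, list(...)), box = box,
                 normal_axis = "z", n_lipids = length(list(...))),
            class = "bilayer_model")
}

# random frame: a posed peptide with n_lipids lipids scattered around it
random_frame <- function(seed, peptide, n_lipids = 5, spread = 1.2) {
  set.seed(seed)
  ctr <- colMeans(peptide_coords(peptide))
  lips <- lapply(seq_len(n_lipids), function(i) {
    lipid_at(i, ctr + runif(3, -spread, spread))
  })
  do.call(frame_of, lips)
}

dist3 <- function(a, b) sqrt(sum((a - b)^2))

# brute-force ambient filter: all-pairs minimum-distance scan
oracle_ambient <- function(peptide, bilayer, cutoff) {
  pa <- peptide$atoms[peptide$atoms$heavy, ]
  out <- integer(0)
  for (id in unique(bilayer$lipids$lipid_id)) {
    li <- bilayer$lipids[bilayer$lipids$lipid_id == id &
                           bilayer$lipids$heavy, ]
    dmin <- Inf
    for (i in seq_len(nrow(pa))) for (j in seq_len(nrow(li))) {
      dmin <- min(dmin, dist3(as.numeric(pa[i, c("x", "y", "z")]),
                              as.numeric(li[j, c("x", "y", "z")])))
    }
    if (dmin <= cutoff) out <- c(out, id)
  }
  out
}

# brute-force side labels: independent half-space construction. The
# descending side is found by rotating a probe point by a small angle in the
# chirality's sense and checking whether its z decreased.
oracle_sides <- function(bilayer, helix, chirality, lipid_ids) {
  u <- helix$axis
  n <- cross3_(u, c(0, 0, 1)); n <- n / sqrt(sum(n^2))
  probe <- helix$centroid + n
  sgn <- if (chirality == "L") -1 else 1
  probe_rot <- rot_(probe - helix$centroid, u, sgn * 0.001) + helix$centroid
  plus_is_desc <- (probe_rot[3] - probe[3]) < 0
  vapply(lipid_ids, function(id) {
    li <- bilayer$lipids[bilayer$lipids$lipid_id == id &
                           bilayer$lipids$role == "c2", ]
    s <- sum((as.numeric(li[1, c("x", "y", "z")]) - helix$centroid) * n)
    if (s == 0) return("ascending")
    if ((s > 0) == plus_is_desc) "descending" else "ascending"
  }, character(1))
}

cross3_ <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])

rot_ <- function(v, u, deg) {
  th <- deg * pi / 180
  u <- u / sqrt(sum(u^2))
  v * cos(th) + cross3_(u, v) * sin(th) + u * sum(u * v) * (1 - cos(th))
}

# brute-force classified contact counts: exhaustive residue x lipid x atom
# triple loop
oracle_contacts <- function(peptide, bilayer, sides, policy) {
  pa <- peptide$atoms[peptide$atoms$heavy, ]
  lab <- setNames(sides$side, sides$lipid_id)
  counts <- c(N_dp = 0, N_dh = 0, N_ah = 0, N_ap = 0)
  for (id in sides$lipid_id) {
    li <- bilayer$lipids[bilayer$lipids$lipid_id == id &
                           bilayer$lipids$heavy, ]
    lcl <- ifelse(li$role == "c2", policy$c2_class, li$role)
    eta <- if (lab[[as.character(id)]] == "descending") "d" else "a"
    for (res in unique(pa$res_id)) {
      ra <- pa[pa$res_id == res, ]
      best_d <- Inf; best_class <- NA
      for (i in seq_len(nrow(ra))) for (j in seq_len(nrow(li))) {
        d <- dist3(as.numeric(ra[i, c("x", "y", "z")]),
                   as.numeric(li[j, c("x", "y", "z")]))
        if (policy$scheme == "strict") {
          want <- if (peptide$polarity[res] == "nonpolar") "tail" else "head"
          if (lcl[j] != want) next
        }
        if (d < best_d) { best_d <- d; best_class <- lcl[j] }
      }
      if (best_d <= policy$contact_cutoff) {
        xi <- if (policy$scheme == "strict") {
          if (peptide$polarity[res] == "nonpolar") "h" else "p"
        } else if (best_class == "tail") "h" else "p"
        key <- paste0("N_", eta, xi)
        counts[key] <- counts[key] + 1
      }
    }
  }
  counts
}
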