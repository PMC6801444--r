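# Internal helpers shared across modules. Units: nm, ns, degrees; energies in
# kBT unless stated otherwise.

# Boltzmann constant times T, in kJ/mol (R = 0.0083144621 kJ/mol/K)
kBT_kJmol <- function(temperature = 303.15) 0.0083144621 * temperature

#' @noRd
wrap_deg <- function(theta) {
  out <- theta %% 360
  out[out == 360] <- 0
  out
}

# smallest circular distance between two angles in degrees, result in [0, 180]
circ_dist_deg <- function(a, b) {
  d <- abs(wrap_deg(a) - wrap_deg(b))
  pmin(d, 360 - d)
}

# signed wrapped difference a - b in (-180, 180]
circ_diff_deg <- function(a, b) {
  d <- (a - b) %% 360
  d[d > 180] <- d[d > 180] - 360
  d
}

unit_vec <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalize a near-zero vector", call. = FALSE)
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Rodrigues rotation of row-matrix xyz about unit axis u by angle (degrees)
rotate_about <- function(xyz, u, angle_deg, origin = c(0, 0, 0)) {
  u <- unit_vec(u)
  th <- angle_deg * pi / 180
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
              3, 3, byrow = TRUE)
  Rm <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  sweep(sweep(xyz, 2, origin) %*% t(Rm), 2, origin, FUN = "+")
}

# pairwise squared distances between row-matrices a (n x 3) and b (m x 3),
# optionally with orthorhombic minimum-image convention
pair_dist2 <- function(a, b, box = NULL) {
  if (is.null(box)) {
    d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
    pmax(d2, 0)
  } else {
    d2 <- matrix(0, nrow(a), nrow(b))
    for (k in 1:3) {
      dk <- outer(a[, k], b[, k], "-")
      if (is.finite(box[k]) && box[k] > 0) dk <- dk - box[k] * round(dk / box[k])
      d2 <- d2 + dk^2
    }
    d2
  }
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# evaluate expr under a fixed RNG seed without disturbing the caller's stream
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
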