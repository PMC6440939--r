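# Low-level vector geometry: dihedrals and internal-coordinate atom
# placement (NeRF), shared by the quality metrics and the structure
# generators.

#' @noRd
vnorm <- function(v) sqrt(sum(v * v))

#' @noRd
unit <- function(v) v / vnorm(v)

#' @noRd
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Dihedral angle over four points, degrees in (-180, 180]
#' @noRd
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

#' Angle at vertex b (degrees)
#' @noRd
bond_angle <- function(a, b, c) {
  v1 <- unit(a - b)
  v2 <- unit(c - b)
  acos(max(-1, min(1, sum(v1 * v2)))) * 180 / pi
}

#' Place atom D given A, B, C with |CD| = bond, angle(B,C,D) = angle and
#' dihedral(A,B,C,D) = torsion (degrees). Natural-extension reference frame.
#' @noRd
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- unit(c - b)
  n <- unit(cross3(b - a, bc))
  m <- cross3(n, bc)
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(tor),
          -bond * sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Deterministic quasi-uniform points on the unit sphere (Fibonacci lattice)
#' @noRd
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(x = sin(phi) * cos(theta),
        y = sin(phi) * sin(theta),
        z = cos(phi))
}

#' Random rigid-body transform helper used by invariance tests
#' @noRd
random_rotation <- function(seed) {
  set.seed(seed)
  m <- matrix(stats::rnorm(9), 3, 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Apply a rotation matrix and translation to a structure's coordinates
#'
#' Rigid-body transform of all atoms (protein and ions). Used mainly to
#' assert that derived metrics are frame-invariant.
#'
#' @param structure an `ldlr_structure`
#' @param rotation 3x3 rotation matrix
#' @param translation length-3 numeric offset (angstrom)
#' @return the transformed `ldlr_structure`
#' @export
transform_structure <- function(structure, rotation = diag(3),
                                translation = c(0, 0, 0)) {
  stopifnot(inherits(structure, "ldlr_structure"))
  xyz <- as.matrix(structure$atoms[, c("x", "y", "z")])
  xyz <- xyz %*% t(rotation)
  xyz <- sweep(xyz, 2, translation, "+")
  structure$atoms$x <- xyz[, 1]
  structure$atoms$y <- xyz[, 2]
  structure$atoms$z <- xyz[, 3]
  structure
}
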