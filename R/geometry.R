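## Internal-coordinate geometry on backbone beads.
## Coordinates are in nm, angles in degrees throughout the package.

.deg <- 180 / pi

.vnorm <- function(v) sqrt(sum(v * v))

.cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Bend angle between three beads
#'
#' Angle at the middle bead `j` of a consecutive backbone triple, computed as
#' the arc cosine of the normalised dot product of the two arm vectors
#' `j -> i` and `j -> k`.
#'
#' @param pi,pj,pk Numeric length-3 coordinates (nm).
#' @return Angle in degrees, in `[0, 180]`.
#' @examples
#' bend_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)) # 90
#' @export
bend_angle <- function(pi, pj, pk) {
  u <- pi - pj
  v <- pk - pj
  nu <- .vnorm(u)
  nv <- .vnorm(v)
  if (nu < 1e-12 || nv < 1e-12) {
    abort("Degenerate geometry: coincident beads in bend angle.",
          class = "cgmelt_degenerate_geometry")
  }
  cosang <- sum(u * v) / (nu * nv)
  cosang <- min(1, max(-1, cosang))
  acos(cosang) * .deg
}

#' Dihedral angle between four beads
#'
#' Four-quadrant (atan2) torsion of the consecutive quadruple i-j-k-l, with the
#' cis (eclipsed) arrangement at 0 degrees and sign given by the handedness of
#' the two bond-plane normals about the central bond.
#'
#' @param pi,pj,pk,pl Numeric length-3 coordinates (nm).
#' @return Angle in degrees, in `(-180, 180]`.
#' @examples
#' dihedral_angle(c(1, 1, 0), c(1, 0, 0), c(-1, 0, 0), c(-1, 1, 0))  # 0 (cis)
#' dihedral_angle(c(1, 1, 0), c(1, 0, 0), c(-1, 0, 0), c(-1, -1, 0)) # 180 (trans)
#' @export
dihedral_angle <- function(pi, pj, pk, pl) {
  b1 <- pj - pi
  b2 <- pk - pj
  b3 <- pl - pk
  n1 <- .cross(b1, b2)
  n2 <- .cross(b2, b3)
  nb2 <- .vnorm(b2)
  if (nb2 < 1e-12 || .vnorm(n1) < 1e-12 || .vnorm(n2) < 1e-12) {
    abort("Undefined dihedral: zero-length bond or collinear triple.",
          class = "cgmelt_degenerate_geometry")
  }
  sinphi <- sum(.cross(n1, n2) * b2) / nb2
  cosphi <- sum(n1 * n2)
  phi <- atan2(sinphi, cosphi) * .deg
  if (phi <= -180) phi <- phi + 360
  phi
}

## Gradient of the bend angle (degrees) w.r.t. the three bead positions.
## Returns a 3 x 3 matrix (rows: beads i, j, k).
.bend_angle_grad <- function(pi, pj, pk) {
  u <- pi - pj
  v <- pk - pj
  nu <- .vnorm(u)
  nv <- .vnorm(v)
  cosang <- min(1, max(-1, sum(u * v) / (nu * nv)))
  sinang <- sqrt(max(0, 1 - cosang^2))
  if (sinang < 1e-8) {
    abort("Degenerate geometry: bend angle at 0 or 180 degrees has no gradient.",
          class = "cgmelt_degenerate_geometry")
  }
  uh <- u / nu
  vh <- v / nv
  di <- (cosang * uh - vh) / (nu * sinang)
  dk <- (cosang * vh - uh) / (nv * sinang)
  g <- rbind(di, -(di + dk), dk)
  rownames(g) <- NULL
  g * .deg
}

## Gradient of the dihedral angle (degrees) w.r.t. the four bead positions.
## Returns a 4 x 3 matrix (rows: beads i, j, k, l).
.dihedral_angle_grad <- function(pi, pj, pk, pl) {
  b1 <- pj - pi
  b2 <- pk - pj
  b3 <- pl - pk
  n1 <- .cross(b1, b2)
  n2 <- .cross(b2, b3)
  nb2 <- .vnorm(b2)
  nn1 <- sum(n1 * n1)
  nn2 <- sum(n2 * n2)
  if (nb2 < 1e-12 || nn1 < 1e-24 || nn2 < 1e-24) {
    abort("Undefined dihedral: zero-length bond or collinear triple.",
          class = "cgmelt_degenerate_geometry")
  }
  di <- -(nb2 / nn1) * n1
  dl <- (nb2 / nn2) * n2
  p <- sum(b1 * b2) / nb2^2
  q <- sum(b3 * b2) / nb2^2
  dj <- -(1 + p) * di + q * dl
  dk <- p * di - (1 + q) * dl
  rbind(di, dj, dk, dl) * .deg
}
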