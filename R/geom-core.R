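## Low-level vector geometry shared by the torsion, builder and orientation
## code. All angles at this level are in degrees unless noted.

DEG <- 180 / pi

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a (near-)zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Angle between two vectors in degrees, in [0, 180]
#' @noRd
vec_angle <- function(a, b) {
  ca <- sum(unit(a) * unit(b))
  acos(min(1, max(-1, ca))) * DEG
}

#' Signed torsion angle defined by four points, in (-180, 180]
#'
#' Standard IUPAC convention: looking from b2 toward b3, the angle from the
#' plane (p1,p2,p3) to the plane (p2,p3,p4), positive clockwise.
#' @noRd
torsion_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  x <- sum(n1 * n2)
  y <- sum(cross3(n1, n2) * unit(b2))
  wrap_angle(atan2(y, x) * DEG)
}

#' Wrap any angle in degrees into (-180, 180]
#' @noRd
wrap_angle <- function(a) {
  w <- a - 360 * floor((a + 180) / 360)
  # floor maps +180 to -180; the convention here keeps +180
  w[w <= -180] <- w[w <= -180] + 360
  w
}

#' Shortest signed angular displacement from `from` to `to`, in (-180, 180]
#' @noRd
ang_delta <- function(from, to) wrap_angle(to - from)

#' Place an atom from three predecessors by internal coordinates (NeRF)
#'
#' @param a,b,c coordinates of the three previously placed atoms; the new
#'   atom d is bonded to c.
#' @param length bond length c-d in Angstrom.
#' @param angle bond angle b-c-d in degrees.
#' @param torsion torsion a-b-c-d in degrees.
#' @noRd
place_atom <- function(a, b, c, length, angle, torsion) {
  ang <- angle / DEG
  tor <- torsion / DEG
  d2 <- c(-length * cos(ang),
          length * sin(ang) * cos(tor),
          length * sin(ang) * sin(tor))
  bc <- unit(c - b)
  n <- unit(cross3(b - a, bc))
  m <- cross3(n, bc)
  # column frame (bc, m, n) rooted at c
  c + c(bc[1] * d2[1] + m[1] * d2[2] + n[1] * d2[3],
        bc[2] * d2[1] + m[2] * d2[2] + n[2] * d2[3],
        bc[3] * d2[1] + m[3] * d2[2] + n[3] * d2[3])
}

#' Rotation matrix sending unit vector `from` onto unit vector `to`
#' @noRd
rotation_between <- function(from, to) {
  f <- unit(from)
  t <- unit(to)
  v <- cross3(f, t)
  c_ <- sum(f * t)
  if (vnorm(v) < 1e-12) {
    if (c_ > 0) return(diag(3))
    # antiparallel: rotate pi about any axis orthogonal to f
    axis <- if (abs(f[1]) < 0.9) unit(cross3(f, c(1, 0, 0))) else unit(cross3(f, c(0, 1, 0)))
    return(rotation_axis(axis, 180))
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

#' Rotation matrix about `axis` by `theta` degrees (Rodrigues)
#' @noRd
rotation_axis <- function(axis, theta) {
  u <- unit(axis)
  th <- theta / DEG
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}
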