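# Internal 3-vector helpers shared by all geometry code.  Points are plain
# numeric length-3 vectors; point sets are n x 3 matrices in Angstrom.

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero vector")
  v / n
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Angle between two vectors, degrees in [0, 180].
vangle <- function(a, b) {
  ca <- sum(unitv(a) * unitv(b))
  acos(max(-1, min(1, ca))) * 180 / pi
}

# Angle between two (unsigned) plane normals folded to [0, 90] degrees.
fold_angle <- function(a, b) {
  ang <- vangle(a, b)
  if (ang > 90) 180 - ang else ang
}

# Rotation matrix for a right-handed rotation of `deg` degrees about `axis`.
rotation_about <- function(axis, deg) {
  u <- unitv(axis)
  th <- deg * pi / 180
  ct <- cos(th); st <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  K <- matrix(c(0, -uz, uy, uz, 0, -ux, -uy, ux, 0), 3, 3, byrow = TRUE)
  diag(3) * ct + st * K + (1 - ct) * (u %o% u)
}

# Apply rotation R (3x3) about `origin` to an n x 3 coordinate matrix.
rotate_coords <- function(xyz, R, origin = c(0, 0, 0)) {
  sweep(sweep(xyz, 2, origin) %*% t(R), 2, origin, `+`)
}

# Signed dihedral a-b-c-d in degrees, IUPAC convention: looking from b to c,
# positive when d is rotated clockwise from a; range (-180, 180].
dihedral <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  m1 <- vcross(n1, unitv(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang + 360 else ang
}

# NeRF-style internal-coordinate placement: position a new atom at `bond`
# Angstrom from C, with angle B-C-new of `angle` degrees and dihedral
# A-B-C-new of `torsion` degrees.
place_atom <- function(a, b, c, bond, angle, torsion) {
  th <- angle * pi / 180
  ph <- torsion * pi / 180
  bc <- unitv(c - b)
  n <- unitv(vcross(b - a, bc))
  m <- vcross(n, bc)
  d2 <- c(-bond * cos(th),
          bond * sin(th) * cos(ph),
          -bond * sin(th) * sin(ph))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Random proper rotation (uniform via QR of Gaussian matrix); used by
# rigid-motion property tests and available to callers of the builders.
random_rotation <- function() {
  q <- qr(matrix(stats::rnorm(9), 3, 3))
  R <- qr.Q(q)
  d <- diag(qr.R(q))
  R <- R %*% diag(sign(d + (d == 0)))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}
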