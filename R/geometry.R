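# Small vector-geometry helpers shared by the builder, the analysis code and
# the tests. Coordinates are n x 3 matrices in Angstroms; angles in radians
# unless a function name says degrees.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

vnorm <- function(v) sqrt(sum(v * v))

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Dihedral angle of four points
#'
#' Signed torsion angle p1-p2-p3-p4 about the p2-p3 axis, in radians in
#' (-pi, pi].
#'
#' @param p1,p2,p3,p4 Numeric length-3 coordinate vectors (Angstroms).
#' @return Dihedral angle in radians.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  atan2(sum(vcross(n1, n2) * b2) / vnorm(b2), sum(n1 * n2))
}

bond_angle <- function(p1, p2, p3) {
  u <- p1 - p2
  v <- p3 - p2
  acos(max(-1, min(1, sum(u * v) / (vnorm(u) * vnorm(v)))))
}

rotation_about_axis <- function(axis, theta) {
  u <- axis / vnorm(axis)
  ct <- cos(theta)
  st <- sin(theta)
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
               3, 3, byrow = TRUE)
  ct * diag(3) + st * ux + (1 - ct) * (u %o% u)
}

# Uniform random rotation matrix (used by property tests).
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / vnorm(q)
  a <- q[1]; b <- q[2]; cc <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - cc^2 - d^2, 2 * (b * cc - a * d), 2 * (b * d + a * cc),
           2 * (b * cc + a * d), a^2 - b^2 + cc^2 - d^2, 2 * (cc * d - a * b),
           2 * (b * d - a * cc), 2 * (cc * d + a * b), a^2 - b^2 - cc^2 + d^2),
         3, 3, byrow = TRUE)
}

raw_rmsd <- function(a, b) sqrt(mean(rowSums((a - b)^2)))
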