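## Small 3D geometry utilities shared by the trajectory, descriptor and
## synthetic modules.  All coordinates in Angstrom.

vnorm <- function(v) sqrt(sum(v^2))
vunit <- function(v) v / vnorm(v)

## Angle (degrees) at vertex b of the triple a-b-c.
angle_deg <- function(a, b, c) {
  u <- vunit(a - b); v <- vunit(c - b)
  acos(max(-1, min(1, sum(u * v)))) * 180 / pi
}

## Signed dihedral (degrees) of the four points p1-p2-p3-p4.
dihedral_deg <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / vnorm(b2)
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

## NeRF atom placement: position of atom D given bonded chain A-B-C, the
## C-D bond length, the B-C-D angle and the A-B-C-D dihedral (degrees).
place_atom <- function(a, b, c, length, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- dihedral * pi / 180
  d_local <- length * c(-cos(ang), sin(ang) * cos(dih),
                        -sin(ang) * sin(dih))
  bc <- vunit(c - b)
  ab <- b - a
  n <- vunit(c(ab[2] * bc[3] - ab[3] * bc[2],
               ab[3] * bc[1] - ab[1] * bc[3],
               ab[1] * bc[2] - ab[2] * bc[1]))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  rot <- cbind(bc, m, n)
  c + drop(rot %*% d_local)
}

## Deterministic near-uniform points on the unit sphere (golden spiral).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(cos(theta) * sin(phi), sin(theta) * sin(phi), cos(phi))
}

## Random rigid rotation matrix (for invariance tests and coil sampling).
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / vnorm(q)
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2),
         3, 3, byrow = TRUE)
}
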