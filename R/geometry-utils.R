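# Internal vector geometry. All functions accept n x 3 matrices and are
# vectorised over rows; single points may be given as length-3 vectors.

.as3 <- function(x) if (is.matrix(x)) x else matrix(x, ncol = 3)

.rowdot <- function(a, b) rowSums(a * b)

.rowcross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

.rownorm <- function(a) sqrt(.rowdot(a, a))

.rowunit <- function(a) a / .rownorm(a)

# IUPAC-signed torsion angle for points a-b-c-d, radians in (-pi, pi].
dihedralAngle <- function(a, b, c, d) {
  a <- .as3(a); b <- .as3(b); c <- .as3(c); d <- .as3(d)
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- .rowcross(b1, b2)
  n2 <- .rowcross(b2, b3)
  m1 <- .rowcross(n1, .rowunit(b2))
  wrapAngle(atan2(-.rowdot(m1, n2), .rowdot(n1, n2)))
}

# Angle at vertex b for points a-b-c, radians.
bondAngle <- function(a, b, c) {
  a <- .as3(a); b <- .as3(b); c <- .as3(c)
  u <- .rowunit(a - b); v <- .rowunit(c - b)
  acos(pmin(1, pmax(-1, .rowdot(u, v))))
}

# Natural-extension (NeRF) placement: new atom D bonded to C with bond length
# r, bond angle theta at C (angle B-C-D) and torsion phi = dihedral(A,B,C,D).
placeAtom <- function(a, b, c, r, theta, phi) {
  bc <- .rowunit(.as3(c) - .as3(b))
  n <- .rowunit(.rowcross(.as3(b) - .as3(a), bc))
  m <- .rowcross(n, bc)
  d <- r * cbind(-cos(theta), sin(theta) * cos(phi), sin(theta) * sin(phi))
  .as3(c) + d[, 1] * bc + d[, 2] * m + d[, 3] * n
}

# Wrap angles into (-pi, pi].
wrapAngle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y <= -pi] <- pi
  y
}

# Deterministic near-uniform points on the unit sphere (golden spiral).
sphereGrid <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}
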