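#' Dihedral angle between four points
#'
#' Computes the torsion angle defined by four points using the standard
#' IUPAC sign convention: looking from `p2` towards `p3`, a clockwise
#' rotation of the far bond relative to the near bond is positive.
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors (coordinates in Angstrom).
#' @return Angle in degrees in (-180, 180].
#' @examples
#' dihedral(c(1, 0, 0), c(0, 0, 0), c(0, 0, 1), c(-1, 0, 1))  # 180
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (vnorm(n1) < 1e-9 || vnorm(n2) < 1e-9) {
    stop("dihedral undefined: three consecutive points are collinear")
  }
  m1 <- cross3(n1, b2 / vnorm(b2))
  ang <- -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  # map -180 -> +180 so the range is (-180, 180]
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Planar angle at a vertex
#'
#' @param a,b,c Numeric 3-vectors; the angle is measured at `b`.
#' @return Angle in degrees in [0, 180].
#' @export
vector_angle <- function(a, b, c) {
  u <- a - b
  v <- c - b
  cosang <- sum(u * v) / (vnorm(u) * vnorm(v))
  acos(max(-1, min(1, cosang))) * 180 / pi
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

vnorm <- function(v) sqrt(sum(v * v))

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap an angle into (-180, 180]
#' @param x Angle(s) in degrees.
#' @return Wrapped angle(s).
#' @export
wrap180 <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y <= -180] <- y[y <= -180] + 360
  # values landing exactly on -180 belong to +180 in a half-open convention
  y[abs(y + 180) < 1e-12] <- 180
  y
}

#' Place an atom from internal coordinates (NeRF construction)
#'
#' Given three reference positions `a`, `b`, `c`, returns the position of a
#' new atom `d` bonded to `c` with the stated bond length, planar angle
#' b-c-d, and torsion a-b-c-d.
#'
#' @param a,b,c Numeric 3-vectors.
#' @param bond Bond length c-d in Angstrom.
#' @param angle Planar angle b-c-d in degrees.
#' @param torsion Torsion a-b-c-d in degrees.
#' @return Numeric 3-vector.
#' @export
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- deg2rad(angle)
  tor <- deg2rad(torsion)
  bc <- c - b
  bc <- bc / vnorm(bc)
  n <- cross3(b - a, bc)
  if (vnorm(n) < 1e-9) stop("place_atom: reference points are collinear")
  n <- n / vnorm(n)
  m <- cross3(n, bc)
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Least-squares superposes `mobile` onto `target` using the SVD-based
#' Kabsch procedure, restricted to proper rotations (det = +1).
#'
#' @param mobile,target Numeric n x 3 matrices of matched coordinates.
#' @return List with `rotation` (3 x 3), `translation` (length 3; the
#'   transformed coordinates are `mobile %*% rotation + translation`),
#'   `rmsd` (Angstrom) and `coords` (the transformed mobile set).
#' @export
kabsch_superpose <- function(mobile, target) {
  mobile <- as.matrix(mobile)
  target <- as.matrix(target)
  stopifnot(ncol(mobile) == 3, ncol(target) == 3)
  if (nrow(mobile) != nrow(target)) {
    stop("kabsch_superpose: coordinate sets must be matched")
  }
  if (nrow(mobile) < 3) stop("kabsch_superpose: need at least 3 atoms")
  cm <- colMeans(mobile)
  ct <- colMeans(target)
  A <- sweep(mobile, 2, cm)
  B <- sweep(target, 2, ct)
  if (sum(svd(A)$d > 1e-8) < 2) {
    stop("kabsch_superpose: degenerate (collinear) geometry")
  }
  H <- t(A) %*% B
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)
  moved <- A %*% R
  rmsd <- sqrt(mean(rowSums((moved - B)^2)))
  list(rotation = R,
       translation = ct - as.vector(cm %*% R),
       rmsd = rmsd,
       coords = sweep(moved, 2, ct, `+`))
}
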