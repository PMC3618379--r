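# Low-level vector geometry shared by the dihedral, superposition and
# fixture-building code. All coordinates are plain numeric length-3
# vectors or n x 3 matrices, in Angstrom.

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

vnorm <- function(v) sqrt(sum(v * v))

#' Dihedral angle of four points
#'
#' Signed torsion angle about the B--C axis, in degrees in (-180, 180].
#' Returns `NA` (with a warning) when the four points are degenerate
#' (collinear segments give a zero-length normal).
#'
#' @param a,b,c,d numeric length-3 coordinate vectors (Angstrom).
#' @return numeric scalar in degrees, or `NA` for degenerate geometry.
#' @export
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (vnorm(n1) < 1e-9 || vnorm(n2) < 1e-9) {
    warning("degenerate (collinear) geometry: dihedral undefined")
    return(NA_real_)
  }
  m1 <- cross3(n1, b2 / vnorm(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

# Place atom D given positions A, B, C, the bond length |C-D|, the angle
# B-C-D (degrees) and the torsion A-B-C-D (degrees). Natural-extension
# (NeRF) construction used by the fixture builder.
place_atom <- function(a, b, c, length, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  d_local <- length * c(-cos(ang), sin(ang) * cos(tor), -sin(ang) * sin(tor))
  bc <- c - b
  bc <- bc / vnorm(bc)
  n <- cross3(b - a, bc)
  n <- n / vnorm(n)
  m <- cross3(n, bc)
  rot <- cbind(bc, m, n)
  c(rot %*% d_local) + c
}

#' Kabsch least-squares superposition
#'
#' Finds the proper rotation and translation minimising the RMSD between
#' two paired coordinate sets, mapping `coords_b` onto `coords_a`.
#' Reflections are corrected through the sign of the determinant of the
#' SVD product, so the returned rotation always has determinant +1.
#'
#' @param coords_a,coords_b n x 3 matrices of paired coordinates
#'   (Angstrom), n >= 3 and not collinear.
#' @return list with `rotation` (3 x 3 proper orthogonal matrix),
#'   `translation` (length-3; the fitted image of `coords_b` is
#'   `coords_b %*% t(rotation) + translation`), and `rmsd` (Angstrom).
#' @export
#' @examples
#' a <- matrix(rnorm(30), 10, 3)
#' fit <- kabsch_superpose(a, a)
#' fit$rmsd  # 0
kabsch_superpose <- function(coords_a, coords_b) {
  coords_a <- as.matrix(coords_a); coords_b <- as.matrix(coords_b)
  if (!all(dim(coords_a) == dim(coords_b)) || ncol(coords_a) != 3L)
    stop("coordinate sets must be equal-size n x 3 matrices")
  n <- nrow(coords_a)
  if (n < 3L) stop("need at least 3 points for superposition")
  ca <- colMeans(coords_a); cb <- colMeans(coords_b)
  A <- sweep(coords_a, 2L, ca)
  B <- sweep(coords_b, 2L, cb)
  H <- t(B) %*% A
  sv <- svd(H)
  if (sv$d[2L] < 1e-10 * max(sv$d[1L], 1e-30))
    stop("rank-deficient (collinear) point set: superposition undefined")
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  fitted <- B %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - A)^2)))
  list(rotation = R,
       translation = ca - c(R %*% cb),
       rmsd = rmsd)
}

# RMSD between two coordinate sets after optimal superposition.
fit_rmsd <- function(coords_a, coords_b) kabsch_superpose(coords_a, coords_b)$rmsd
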