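# Low-level rigid-body geometry shared by the builder and the analyser.

.deg <- function(x) x * 180 / pi
.rad <- function(x) x * pi / 180

.clamp1 <- function(x) pmin(1, pmax(-1, x))

.normalize <- function(v) {
  n <- sqrt(sum(v * v))
  if (n < 1e-14) stop("cannot normalize a zero-length vector")
  v / n
}

.cross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues rotation by \code{theta} radians about the unit axis \code{u}.
#' Used as a premultiplier on column vectors expressed in the lab frame.
#'
#' @param u unit 3-vector (normalised internally).
#' @param theta rotation angle in radians.
#' @return 3x3 orthonormal rotation matrix.
#' @keywords internal
rot_axis <- function(u, theta) {
  u <- .normalize(u)
  ct <- cos(theta); st <- sin(theta)
  ux <- u[1L]; uy <- u[2L]; uz <- u[3L]
  K <- matrix(c(0, uz, -uy,
                -uz, 0, ux,
                uy, -ux, 0), 3L, 3L)
  diag(3L) * ct + st * K + (1 - ct) * tcrossprod(u)
}

rot_z <- function(theta) {
  ct <- cos(theta); st <- sin(theta)
  matrix(c(ct, st, 0, -st, ct, 0, 0, 0, 1), 3L, 3L)
}

# 180 degree flip about the base-frame x axis, applied to a Crick base frame
# before pairing so that both frames share the pair z sense.
.flip_x <- diag(c(1, -1, -1))

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation \code{R} and translation \code{t} minimising
#' \code{sum(|R x_i + t - y_i|^2)} over matched coordinate rows, via SVD of the
#' covariance matrix with the usual determinant correction, so a reflection is
#' never returned.
#'
#' @param x,y n x 3 coordinate matrices (same row order; n >= 3 and
#'   non-collinear for a unique rotation).
#' @return list with \code{R} (3x3), \code{t} (length 3), and \code{rmsd} of
#'   the superposed coordinates.
#' @export
kabsch <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (!all(dim(x) == dim(y)) || ncol(x) != 3L)
    stop("x and y must be matched n x 3 coordinate matrices")
  if (nrow(x) < 3L)
    stop("at least 3 matched atoms are required for a rigid superposition")
  cx <- colMeans(x); cy <- colMeans(y)
  xc <- sweep(x, 2L, cx); yc <- sweep(y, 2L, cy)
  s <- svd(crossprod(xc, yc))           # H = Xc' Yc ;  H = U D V'
  d <- sign(det(tcrossprod(s$v, s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t <- cy - drop(R %*% cx)
  fitted <- sweep(tcrossprod(xc, R), 2L, cy, "+")
  rmsd <- sqrt(mean(rowSums((fitted - y)^2)))
  # guard against a collinear atom set (rotation about the line undetermined)
  if (s$d[2L] < 1e-9 * max(s$d[1L], 1))
    stop("matched atoms are (near-)collinear; frame is underdetermined")
  list(R = R, t = t, rmsd = rmsd)
}

#' Signed torsion angle
#'
#' Dihedral p1-p2-p3-p4 in degrees, in (-180, 180], with the IUPAC sign
#' convention (positive clockwise looking from p2 to p3).
#'
#' @param p1,p2,p3,p4 3-vectors.
#' @return angle in degrees.
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .cross(b1, b2); n2 <- .cross(b2, b3)
  m1 <- .cross(n1, .normalize(b2))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2))
  wrap_angle(.deg(ang))
}

# Place a fourth atom from internal coordinates (NeRF construction):
# bond length r to c, angle theta (deg) a-c-new? -- here angle is at c between
# c->b and c->new; torsion chi (deg) is the dihedral new-c-b-a.
place_atom_zmat <- function(a, b, c, r, theta, chi) {
  theta <- .rad(theta); chi <- .rad(chi)
  bc <- .normalize(c - b)
  n <- .normalize(.cross(b - a, bc))
  m <- .cross(n, bc)
  # local displacement from c; sign chosen so dihedral(a, b, c, new) == chi
  d <- r * (-cos(theta) * bc + sin(theta) * (cos(chi) * m - sin(chi) * n))
  c + d
}

#' Wrap angles into (-180, 180]
#' @param x angle(s) in degrees.
#' @return wrapped angle(s).
#' @export
wrap_angle <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}
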