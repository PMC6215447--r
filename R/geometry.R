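#' Rotation matrix about a coordinate axis
#'
#' Right-handed rotation matrices about the global axes, used throughout the
#' kinematic chain. Angles are in degrees.
#'
#' @param theta angle in degrees.
#' @return 3x3 rotation matrix.
#' @keywords internal
rot_x <- function(theta) {
  t <- theta * pi / 180
  c <- cos(t); s <- sin(t)
  matrix(c(1, 0, 0,
           0, c, -s,
           0, s, c), 3, 3, byrow = TRUE)
}

#' @rdname rot_x
#' @keywords internal
rot_y <- function(theta) {
  t <- theta * pi / 180
  c <- cos(t); s <- sin(t)
  matrix(c(c, 0, s,
           0, 1, 0,
           -s, 0, c), 3, 3, byrow = TRUE)
}

#' @rdname rot_x
#' @keywords internal
rot_z <- function(theta) {
  t <- theta * pi / 180
  c <- cos(t); s <- sin(t)
  matrix(c(c, -s, 0,
           s, c, 0,
           0, 0, 1), 3, 3, byrow = TRUE)
}

#' Rotation about an arbitrary unit axis (Rodrigues)
#'
#' @param axis unit 3-vector.
#' @param theta angle in degrees.
#' @return 3x3 rotation matrix.
#' @keywords internal
rot_axis <- function(axis, theta) {
  axis <- axis / sqrt(sum(axis^2))
  t <- theta * pi / 180
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(t) * K + (1 - cos(t)) * (K %*% K)
}

#' Rigid transform (rotation + translation)
#'
#' A minimal rigid-transform representation used for segment poses. The
#' transform maps local coordinates p to global R p + t.
#'
#' @param R 3x3 rotation matrix.
#' @param t length-3 translation.
#' @return list with elements `R` and `t`, class `rigid_transform`.
#' @export
rigid_transform <- function(R = diag(3), t = c(0, 0, 0)) {
  stopifnot(is.matrix(R), all(dim(R) == c(3, 3)), length(t) == 3)
  structure(list(R = R, t = as.numeric(t)), class = "rigid_transform")
}

#' Compose two rigid transforms (a then applied after b: a %t% b maps p to
#' a(b(p)))
#' @param a,b rigid transforms.
#' @return composed rigid transform.
#' @keywords internal
compose_transform <- function(a, b) {
  rigid_transform(a$R %*% b$R, as.numeric(a$R %*% b$t) + a$t)
}

#' Apply a rigid transform to points
#' @param tr rigid transform.
#' @param pts n x 3 matrix (or length-3 vector).
#' @return transformed points, same shape.
#' @export
apply_transform <- function(tr, pts) {
  if (is.null(dim(pts))) {
    return(as.numeric(tr$R %*% pts) + tr$t)
  }
  t(tr$R %*% t(pts)) + matrix(tr$t, nrow(pts), 3, byrow = TRUE)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

norm3 <- function(v) sqrt(sum(v^2))

unit3 <- function(v) {
  n <- norm3(v)
  if (n == 0) stop("cannot normalize a zero vector")
  v / n
}

#' Algebraic least-squares sphere fit
#'
#' Fits a sphere to a point cloud by linear least squares on the algebraic
#' form |p|^2 = 2 c.p + (r^2 - |c|^2). Exact for noiseless spherical data;
#' for noisy data it is the standard algebraic (Coope) estimator. Used to
#' locate the hip joint centre from femoral-head surface points and to size
#' the condylar comparison regions.
#'
#' @param points n x 3 matrix of point coordinates (n >= 4, non-coplanar).
#' @return list with `centre` (length 3) and `radius`.
#' @examples
#' p <- rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))
#' fit_sphere(p)
#' @export
fit_sphere <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 4) stop("sphere fit needs at least 4 points")
  A <- cbind(2 * points, 1)
  b <- rowSums(points^2)
  qr_A <- qr(A)
  if (qr_A$rank < 4) stop("sphere fit failure: degenerate (coplanar or collinear) points")
  sol <- qr.coef(qr_A, b)
  centre <- sol[1:3]
  r2 <- sol[4] + sum(centre^2)
  if (r2 <= 0) stop("sphere fit failure: non-positive squared radius")
  list(centre = as.numeric(centre), radius = sqrt(r2))
}

#' Deterministic quasi-uniform points on a sphere (Fibonacci lattice)
#'
#' @param n number of points.
#' @param centre sphere centre.
#' @param radius sphere radius.
#' @return n x 3 matrix.
#' @keywords internal
fibonacci_sphere <- function(n, centre = c(0, 0, 0), radius = 1) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  golden <- pi * (1 + sqrt(5))
  theta <- golden * i
  pts <- cbind(cos(theta) * sin(phi), sin(theta) * sin(phi), cos(phi))
  pts * radius + matrix(centre, n, 3, byrow = TRUE)
}
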