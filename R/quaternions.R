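#' Quaternion utilities
#'
#' Minimal unit-quaternion toolbox used throughout the pipeline. Quaternions
#' are length-4 numeric vectors in scalar-first order `(w, x, y, z)`; they
#' represent rotations of vectors from the body frame into the reference
#' frame. On-disk trajectory files use the scalar-last `(qx, qy, qz, qw)`
#' layout; conversion happens in the readers/writers.
#'
#' @param q,q1,q2 unit quaternions, `c(w, x, y, z)`.
#' @name quaternions
NULL

#' @rdname quaternions
#' @export
quat_identity <- function() c(1, 0, 0, 0)

#' @rdname quaternions
#' @export
quat_normalize <- function(q) {
  n <- sqrt(sum(q^2))
  if (n == 0) stop("cannot normalize a zero quaternion")
  q / n
}

#' @rdname quaternions
#' @export
quat_conjugate <- function(q) c(q[1], -q[2], -q[3], -q[4])

#' @rdname quaternions
#' @export
quat_multiply <- function(q1, q2) {
  w1 <- q1[1]; x1 <- q1[2]; y1 <- q1[3]; z1 <- q1[4]
  w2 <- q2[1]; x2 <- q2[2]; y2 <- q2[3]; z2 <- q2[4]
  c(w1 * w2 - x1 * x2 - y1 * y2 - z1 * z2,
    w1 * x2 + x1 * w2 + y1 * z2 - z1 * y2,
    w1 * y2 - x1 * z2 + y1 * w2 + z1 * x2,
    w1 * z2 + x1 * y2 - y1 * x2 + z1 * w2)
}

#' @rdname quaternions
#' @export
quat_to_rotmat <- function(q) {
  q <- quat_normalize(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' @rdname quaternions
#' @export
rotmat_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s, (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] > R[2, 2] && R[1, 1] > R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s, (R[1, 2] + R[2, 1]) / s, (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] > R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, 0.25 * s, (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s, (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  quat_normalize(q)
}

#' @rdname quaternions
#' @param rotvec rotation vector (axis times angle, radians).
#' @export
quat_exp_map <- function(rotvec) {
  th <- sqrt(sum(rotvec^2))
  if (th < 1e-12) {
    quat_normalize(c(1, rotvec / 2))
  } else {
    c(cos(th / 2), sin(th / 2) * rotvec / th)
  }
}

#' @rdname quaternions
#' @export
quat_log_map <- function(q) {
  q <- quat_normalize(q)
  if (q[1] < 0) q <- -q
  v <- q[2:4]
  nv <- sqrt(sum(v^2))
  if (nv < 1e-12) return(2 * v)
  2 * atan2(nv, q[1]) * v / nv
}

#' @rdname quaternions
#' @param u interpolation fraction in `[0, 1]`.
#' @export
quat_slerp <- function(q1, q2, u) {
  d <- sum(q1 * q2)
  if (d < 0) { q2 <- -q2; d <- -d }
  if (d > 1 - 1e-12) {
    return(quat_normalize(q1 + u * (q2 - q1)))
  }
  th <- acos(pmin(1, d))
  (sin((1 - u) * th) * q1 + sin(u * th) * q2) / sin(th)
}

#' @rdname quaternions
#' @param pts numeric matrix of 3D points, one per row (or length-3 vector).
#' @export
quat_rotate <- function(q, pts) {
  R <- quat_to_rotmat(q)
  if (is.matrix(pts)) pts %*% t(R) else as.numeric(R %*% pts)
}

# skew-symmetric cross-product matrix
skew3 <- function(v) {
  matrix(c(0, -v[3], v[2],
           v[3], 0, -v[1],
           -v[2], v[1], 0), nrow = 3, byrow = TRUE)
}

#' Rigid pose
#'
#' A rigid transform `(q, t)` mapping body-frame coordinates into the
#' reference frame: `x_ref = R(q) x_body + t`.
#'
#' @param t translation, metres (length 3).
#' @param q unit quaternion `(w, x, y, z)`.
#' @export
pose <- function(t = c(0, 0, 0), q = quat_identity()) {
  stopifnot(length(t) == 3, length(q) == 4)
  structure(list(t = as.numeric(t), q = quat_normalize(q)), class = "se3_pose")
}

#' @rdname pose
#' @param p1,p2 poses; `pose_compose(p1, p2)` applies `p2` then `p1`.
#' @export
pose_compose <- function(p1, p2) {
  pose(t = p1$t + quat_rotate(p1$q, p2$t), q = quat_multiply(p1$q, p2$q))
}

#' @rdname pose
#' @export
pose_inverse <- function(p1) {
  qi <- quat_conjugate(p1$q)
  pose(t = -quat_rotate(qi, p1$t), q = qi)
}

#' @rdname pose
#' @param pts points (rows) in the body frame.
#' @export
pose_apply <- function(p1, pts) {
  out <- quat_rotate(p1$q, pts)
  if (is.matrix(out)) sweep(out, 2, p1$t, "+") else out + p1$t
}
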