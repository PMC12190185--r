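# Small 3-vector helpers shared across the mechanical modules. Kept base-R
# and allocation-light: they run once per source per frame in the pipeline.

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

vnorm <- function(v) sqrt(sum(v * v))

unit3 <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a near-zero vector", call. = FALSE)
  v / n
}

# Rotation matrices about the tibial-frame axes (angles in radians).
# rot_x: frontal plane (adduction/varus-positive), rot_z: sagittal plane
# (flexion), rot_y: transverse plane (internal rotation).
rot_x <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(1, 0, 0, 0, ca, sa, 0, -sa, ca), 3L, 3L)
}

rot_y <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, 0, -sa, 0, 1, 0, sa, 0, ca), 3L, 3L)
}

rot_z <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3L, 3L)
}

deg2rad <- function(d) d * pi / 180

# Quaternion (w, x, y, z) <-> rotation matrix, used by the trial CSV schema
# to carry the lab->tibial orientation.
quat_to_mat <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)
  ), 3L, 3L)
}

mat_to_quat <- function(R) {
  tr <- R[1L, 1L] + R[2L, 2L] + R[3L, 3L]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s,
           (R[3L, 2L] - R[2L, 3L]) / s,
           (R[1L, 3L] - R[3L, 1L]) / s,
           (R[2L, 1L] - R[1L, 2L]) / s)
  } else {
    i <- which.max(c(R[1L, 1L], R[2L, 2L], R[3L, 3L]))
    if (i == 1L) {
      s <- sqrt(1 + R[1L, 1L] - R[2L, 2L] - R[3L, 3L]) * 2
      q <- c((R[3L, 2L] - R[2L, 3L]) / s, 0.25 * s,
             (R[1L, 2L] + R[2L, 1L]) / s, (R[1L, 3L] + R[3L, 1L]) / s)
    } else if (i == 2L) {
      s <- sqrt(1 + R[2L, 2L] - R[1L, 1L] - R[3L, 3L]) * 2
      q <- c((R[1L, 3L] - R[3L, 1L]) / s, (R[1L, 2L] + R[2L, 1L]) / s,
             0.25 * s, (R[2L, 3L] + R[3L, 2L]) / s)
    } else {
      s <- sqrt(1 + R[3L, 3L] - R[1L, 1L] - R[2L, 2L]) * 2
      q <- c((R[2L, 1L] - R[1L, 2L]) / s, (R[1L, 3L] + R[3L, 1L]) / s,
             (R[2L, 3L] + R[3L, 2L]) / s, 0.25 * s)
    }
  }
  if (q[1L] < 0) q <- -q
  q
}

stopifnot_finite <- function(x, what) {
  if (!all(is.finite(x))) {
    stop("non-finite value in ", what, call. = FALSE)
  }
  invisible(x)
}
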