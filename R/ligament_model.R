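#' Slack (zero-load) length of a ligament bundle
#'
#' Calibrates a bundle's slack length from its attachment-to-attachment
#' distance at the model's full-extension reference pose and its reference
#' strain there. By construction a bundle of length `reference_length` then
#' carries strain exactly `eps_r`.
#'
#' @param reference_length Attachment distance at full extension (m), > 0.
#' @param eps_r Dimensionless strain at full extension, > -1. Negative
#'   values mean the bundle is slack when the knee is fully extended.
#' @return Zero-load (slack) length in metres:
#'   `reference_length / (1 + eps_r)`.
#' @examples
#' zero_load_length(0.105, 0.05) # 0.100
#' @export
zero_load_length <- function(reference_length, eps_r) {
  if (any(!is.finite(reference_length)) || any(reference_length <= 0)) {
    stop("invalid parameter: reference_length must be finite and > 0",
         call. = FALSE)
  }
  if (any(!is.finite(eps_r)) || any(eps_r <= -1)) {
    stop("invalid parameter: eps_r must be finite and > -1", call. = FALSE)
  }
  reference_length / (1 + eps_r)
}

#' Engineering strain of a ligament bundle
#'
#' @param length Current attachment-to-attachment distance (m), >= 0.
#' @param zero_load_length Slack length (m), > 0.
#' @return Dimensionless strain `(length - zero_load_length) /
#'   zero_load_length`; negative when the bundle is slack.
#' @export
bundle_strain <- function(length, zero_load_length) {
  if (any(!is.finite(zero_load_length)) || any(zero_load_length <= 0)) {
    stop("invalid parameter: zero_load_length must be finite and > 0",
         call. = FALSE)
  }
  if (any(!is.finite(length)) || any(length < 0)) {
    stop("invalid parameter: length must be finite and >= 0", call. = FALSE)
  }
  (length - zero_load_length) / zero_load_length
}

#' Piecewise nonlinear-elastic bundle force
#'
#' Tensile force of a ligament bundle as a function of strain: zero below
#' slack, a quadratic "toe" region `k * eps^2 / (4 * eps_lim)` for
#' `0 <= eps <= 2 * eps_lim`, and a linear region `k * (eps - eps_lim)`
#' beyond. The two loaded branches meet with continuous value and slope at
#' `eps = 2 * eps_lim`, so the force is non-negative and non-decreasing.
#'
#' @param eps Dimensionless strain (vectorized).
#' @param k Bundle stiffness, N per unit strain, > 0.
#' @param eps_lim Reference linear strain limit, > 0. Default 0.03.
#' @return Tensile force in newtons, >= 0.
#' @examples
#' bundle_force(0.10, k = 1000, eps_lim = 0.03) # 70
#' bundle_force(0.02, k = 1000, eps_lim = 0.03) # 10/3
#' @export
bundle_force <- function(eps, k, eps_lim = 0.03) {
  if (any(!is.finite(eps))) {
    stop("invalid input: non-finite strain", call. = FALSE)
  }
  if (any(!is.finite(k)) || any(k <= 0)) {
    stop("invalid parameter: k must be finite and > 0", call. = FALSE)
  }
  if (any(!is.finite(eps_lim)) || any(eps_lim <= 0)) {
    stop("invalid parameter: eps_lim must be finite and > 0", call. = FALSE)
  }
  n <- max(length(eps), length(k), length(eps_lim))
  eps <- rep_len(eps, n); k <- rep_len(k, n); eps_lim <- rep_len(eps_lim, n)
  f <- numeric(n)
  toe <- eps >= 0 & eps <= 2 * eps_lim
  lin <- eps > 2 * eps_lim
  f[toe] <- k[toe] * eps[toe]^2 / (4 * eps_lim[toe])
  f[lin] <- k[lin] * (eps[lin] - eps_lim[lin])
  f
}

#' Straight-line bundle line of action
#'
#' A bundle's path is a straight line between its attachments; under tension
#' it pulls the tibia toward the femur. The returned primitive is the pull on
#' the tibia: application point at the tibial attachment, unit direction from
#' the tibial toward the femoral attachment. (When assembling decomposition
#' sources, [ligament_sources()] uses the equal-and-opposite pull on the
#' femoral side of the joint, which shares this line of action.)
#'
#' @param femoral_attachment Femoral attachment, 3-vector (m), expressed in
#'   the tibial frame at the current pose.
#' @param tibial_attachment Tibial attachment, 3-vector (m), tibial frame.
#' @return List with `point` (tibial attachment) and unit `direction`.
#' @export
bundle_line_of_action <- function(femoral_attachment, tibial_attachment) {
  stopifnot_finite(femoral_attachment, "femoral_attachment")
  stopifnot_finite(tibial_attachment, "tibial_attachment")
  d <- femoral_attachment - tibial_attachment
  len <- vnorm(d)
  if (len < 1e-9) {
    stop("degenerate geometry: coincident ligament attachments",
         call. = FALSE)
  }
  list(point = as.numeric(tibial_attachment), direction = as.numeric(d / len))
}

ligament_levels <- c("ACL", "PCL", "MCL", "LCL", "MPFL", "LPFL",
                     "ALL", "PML", "POL", "PFL")

# 3-column attachment coordinates as parsed by jsonlite (matrix or list of
# length-3 vectors, depending on the record layout).
json_mat3 <- function(x) {
  if (is.matrix(x)) return(x)
  if (is.list(x)) return(do.call(rbind, x))
  matrix(x, ncol = 3L)
}

default_bundle_counts <- c(ACL = 2L, PCL = 2L, MCL = 5L, LCL = 3L,
                           MPFL = 3L, LPFL = 3L, ALL = 1L, PML = 1L,
                           POL = 1L, PFL = 1L)

#' Validate and calibrate a ligament bundle parameter set
#'
#' Checks the parameter table (one row per bundle) and calibrates each
#' bundle's reference length (attachment distance at the full-extension
#' pose, where femoral and tibial frames coincide) and zero-load length via
#' [zero_load_length()].
#'
#' @param params Data frame with columns `bundle_id`, `ligament`, `k` (N),
#'   `eps_r`, `eps_lim`, femoral attachment `fx, fy, fz` and tibial (or, for
#'   the patellofemoral ligaments, patellar) attachment `tx, ty, tz` in
#'   metres, tibial frame, right-knee convention.
#' @return The table with `reference_length` and `zero_load_length` columns
#'   appended, classed `"ligament_set"`.
#' @export
ligament_set <- function(params) {
  need <- c("bundle_id", "ligament", "k", "eps_r", "eps_lim",
            "fx", "fy", "fz", "tx", "ty", "tz")
  missing_cols <- setdiff(need, names(params))
  if (length(missing_cols)) {
    stop("ligament parameter table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  params <- as.data.frame(params)[, union(need, names(params))]
  if (anyDuplicated(params$bundle_id)) {
    stop("duplicate bundle_id in ligament parameter table", call. = FALSE)
  }
  bad_lig <- setdiff(unique(params$ligament), ligament_levels)
  if (length(bad_lig)) {
    stop("unknown ligament name(s): ", paste(bad_lig, collapse = ", "),
         call. = FALSE)
  }
  if (any(params$k <= 0) || any(params$eps_lim <= 0) ||
      any(params$eps_r <= -1)) {
    stop("invalid parameter: require k > 0, eps_lim > 0, eps_r > -1",
         call. = FALSE)
  }
  fem <- as.matrix(params[, c("fx", "fy", "fz")])
  tib <- as.matrix(params[, c("tx", "ty", "tz")])
  stopifnot_finite(fem, "femoral attachments")
  stopifnot_finite(tib, "tibial attachments")
  params$reference_length <- sqrt(rowSums((fem - tib)^2))
  if (any(params$reference_length < 1e-9)) {
    stop("degenerate geometry: coincident ligament attachments",
         call. = FALSE)
  }
  params$zero_load_length <-
    zero_load_length(params$reference_length, params$eps_r)
  class(params) <- c("ligament_set", "data.frame")
  params
}

#' Default knee ligament parameter set (10 ligaments, 22 bundles)
#'
#' An idealized, condyle-scaled right-knee geometry with
#' literature-plausible placeholder stiffness and reference-strain values:
#' anterior/posterior cruciates (2 + 2 bundles), medial/lateral collaterals
#' (5 + 3), medial/lateral patellofemoral ligaments (3 + 3, routed to a
#' patella treated as co-moving with the tibial extensor path),
#' anterolateral ligament, posteromedial ligament, posterior oblique
#' ligament and popliteofibular ligament (1 each). Coordinates are metres in
#' the tibial frame (x anterior, y proximal, z medial, origin at the knee
#' joint centre); the set is fully overridable via a user JSON file (see
#' [read_ligament_params()]).
#'
#' @return A calibrated [ligament_set()].
#' @export
default_ligament_params <- function() {
  tab <- read.csv(text = "
bundle_id,ligament,k,eps_r,fx,fy,fz,tx,ty,tz
ACL_am,ACL,2600,0.030,-0.008,0.012,-0.006,0.015,-0.015,0.002
ACL_pl,ACL,2400,0.050,-0.010,0.008,-0.008,0.012,-0.015,-0.004
PCL_al,PCL,3200,-0.020,0.002,0.010,0.008,-0.022,-0.020,0.000
PCL_pm,PCL,2800,-0.010,-0.002,0.006,0.010,-0.020,-0.022,0.004
MCL_sa,MCL,2500,0.030,0.000,0.012,0.042,0.008,-0.065,0.030
MCL_si,MCL,2500,0.035,-0.002,0.012,0.043,0.002,-0.060,0.032
MCL_sp,MCL,2200,0.030,-0.006,0.011,0.042,-0.008,-0.055,0.032
MCL_da,MCL,1600,0.020,0.002,0.010,0.040,0.005,-0.018,0.038
MCL_dp,MCL,1600,0.020,-0.005,0.010,0.040,-0.005,-0.018,0.038
LCL_a,LCL,2200,0.012,0.002,0.012,-0.042,-0.003,-0.048,-0.038
LCL_i,LCL,2200,0.010,-0.001,0.012,-0.043,-0.006,-0.048,-0.038
LCL_p,LCL,2000,0.008,-0.005,0.011,-0.042,-0.010,-0.047,-0.037
MPFL_s,MPFL,800,0.000,0.004,0.018,0.040,0.038,0.022,0.016
MPFL_i,MPFL,800,0.000,0.004,0.015,0.041,0.040,0.016,0.018
MPFL_d,MPFL,700,-0.010,0.004,0.012,0.041,0.041,0.010,0.018
LPFL_s,LPFL,800,0.000,0.004,0.018,-0.040,0.038,0.022,-0.016
LPFL_i,LPFL,800,0.000,0.004,0.015,-0.041,0.040,0.016,-0.018
LPFL_d,LPFL,700,-0.010,0.004,0.012,-0.041,0.041,0.010,-0.018
ALL,ALL,1500,0.005,-0.002,0.010,-0.043,0.012,-0.025,-0.035
PML,PML,1600,0.025,-0.010,0.010,0.035,-0.018,-0.020,0.030
POL,POL,1800,0.030,-0.006,0.014,0.038,-0.020,-0.025,0.028
PFL,PFL,2000,0.010,-0.006,0.008,-0.040,-0.015,-0.045,-0.036
", stringsAsFactors = FALSE)
  tab$eps_lim <- 0.03
  ligament_set(tab)
}

#' Knee pose (3-DOF rotation of the femur in the tibial frame)
#'
#' The knee is a 3-degree-of-freedom joint: flexion (sagittal), adduction
#' (frontal, varus-positive) and internal rotation (transverse), composed
#' about the knee joint centre. The full-extension reference pose is all
#' angles zero, where the femoral frame coincides with the tibial frame.
#'
#' @param flexion_deg,adduction_deg,rotation_deg Knee angles in degrees;
#'   adduction is varus-positive (positive values open the lateral joint
#'   space and strain the lateral structures).
#' @return Object of class `"knee_pose"` carrying the angles and the 3x3
#'   rotation `R` placing femoral-frame points in the tibial frame.
#' @export
knee_pose <- function(flexion_deg = 0, adduction_deg = 0, rotation_deg = 0) {
  ang <- c(flexion = flexion_deg, adduction = adduction_deg,
           rotation = rotation_deg)
  stopifnot_finite(ang, "knee angles")
  R <- rot_x(deg2rad(adduction_deg)) %*%
    rot_z(-deg2rad(flexion_deg)) %*%
    rot_y(deg2rad(rotation_deg))
  structure(list(flexion_deg = flexion_deg, adduction_deg = adduction_deg,
                 rotation_deg = rotation_deg, R = R),
            class = "knee_pose")
}

# Fast internal path: bundle lengths, strains, forces and on-femur force
# vectors for one pose. Returns a list of plain vectors/matrices.
ligament_state_core <- function(R, params) {
  fem0 <- as.matrix(params[, c("fx", "fy", "fz")])
  tib <- as.matrix(params[, c("tx", "ty", "tz")])
  fem <- fem0 %*% t(R)
  d <- tib - fem                      # femoral attachment -> tibial attachment
  len <- sqrt(rowSums(d^2))
  eps <- (len - params$zero_load_length) / params$zero_load_length
  f <- bundle_force(eps, params$k, params$eps_lim)
  dir_fem <- d / len                  # pull on the femoral side of the joint
  list(length = len, strain = eps, force = f,
       point = fem, direction = dir_fem)
}

#' Ligament force sources at a knee pose
#'
#' Evaluates every bundle of a calibrated [ligament_set()] at a pose:
#' femoral (and patellar-routed) attachments are placed in the tibial frame,
#' strains follow from the calibrated slack lengths, forces from
#' [bundle_force()]. Each bundle yields one decomposition force source in
#' the on-femur convention (see the package overview): the force is the pull
#' the tensioned bundle exerts on the femoral side of the joint, applied at
#' the femoral attachment and directed along the straight-line path toward
#' the tibial attachment. Slack bundles are retained with zero force and
#' flagged.
#'
#' @param pose A [knee_pose()].
#' @param params A calibrated [ligament_set()]; defaults to
#'   [default_ligament_params()].
#' @return A force-source data frame (see [force_source()]) with extra
#'   columns `length`, `strain`, `force` and `slack`.
#' @export
ligament_sources <- function(pose, params = default_ligament_params()) {
  if (!inherits(pose, "knee_pose")) {
    stop("configuration error: `pose` must be a knee_pose ",
         "(missing femoral-to-tibial transform)", call. = FALSE)
  }
  if (!inherits(params, "ligament_set")) params <- ligament_set(params)
  st <- ligament_state_core(pose$R, params)
  Fvec <- st$direction * st$force
  out <- data.frame(
    source_id = params$bundle_id,
    category = "ligament",
    px = st$point[, 1L], py = st$point[, 2L], pz = st$point[, 3L],
    fx = Fvec[, 1L], fy = Fvec[, 2L], fz = Fvec[, 3L],
    cx = 0, cy = 0, cz = 0,
    length = st$length, strain = st$strain, force = st$force,
    slack = st$strain < 0,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Read / write ligament bundle parameters (JSON)
#'
#' One JSON record per bundle with fields matching the [ligament_set()]
#' columns: `bundle_id`, `ligament`, `k` (N), `eps_r`, `eps_lim`
#' (dimensionless), `femoral_attachment` and `tibial_attachment` (3-vectors,
#' metres).
#'
#' @param path File path.
#' @return `read_ligament_params()` returns a calibrated [ligament_set()];
#'   `write_ligament_params()` returns `path` invisibly.
#' @export
read_ligament_params <- function(path) {
  rec <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  fem <- json_mat3(rec$femoral_attachment)
  tib <- json_mat3(rec$tibial_attachment)
  tab <- data.frame(
    bundle_id = rec$bundle_id, ligament = rec$ligament,
    k = rec$k, eps_r = rec$eps_r, eps_lim = rec$eps_lim,
    fx = fem[, 1L], fy = fem[, 2L], fz = fem[, 3L],
    tx = tib[, 1L], ty = tib[, 2L], tz = tib[, 3L],
    stringsAsFactors = FALSE
  )
  ligament_set(tab)
}

#' @rdname read_ligament_params
#' @param params A [ligament_set()] (or coercible data frame).
#' @export
write_ligament_params <- function(params, path) {
  if (!inherits(params, "ligament_set")) params <- ligament_set(params)
  rec <- data.frame(bundle_id = params$bundle_id, ligament = params$ligament,
                    k = params$k, eps_r = params$eps_r,
                    eps_lim = params$eps_lim, stringsAsFactors = FALSE)
  rec$femoral_attachment <- unname(as.matrix(params[, c("fx", "fy", "fz")]))
  rec$tibial_attachment <- unname(as.matrix(params[, c("tx", "ty", "tz")]))
  jsonlite::write_json(rec, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}
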