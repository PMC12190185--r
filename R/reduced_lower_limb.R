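#' Anthropometry for the reduced foot + shank model
#'
#' Segment inertial parameters from standard proportional anthropometry
#' tables (fractions of body mass / height), configurable per subject.
#'
#' @param body_mass Body mass (kg), > 0.
#' @param height Stature (m), > 0.
#' @param shank_mass_frac,foot_mass_frac Segment masses as fractions of body
#'   mass (defaults 0.0465 and 0.0145).
#' @param shank_length_frac Shank length as fraction of height (0.246).
#' @param shank_com_frac Shank centre-of-mass position as fraction of the
#'   knee-to-ankle distance from the knee (0.433).
#' @param intercondylar_width_frac Intercondylar width as fraction of height
#'   (0.029); sets the default two-point contact separation.
#' @return Object of class `"anthropometry"`.
#' @export
anthropometry <- function(body_mass, height,
                          shank_mass_frac = 0.0465,
                          foot_mass_frac = 0.0145,
                          shank_length_frac = 0.246,
                          shank_com_frac = 0.433,
                          intercondylar_width_frac = 0.029) {
  if (body_mass <= 0 || height <= 0) {
    stop("invalid parameter: body_mass and height must be > 0",
         call. = FALSE)
  }
  fr <- c(shank_mass_frac, foot_mass_frac, shank_length_frac,
          shank_com_frac, intercondylar_width_frac)
  if (any(fr <= 0) || any(fr >= 1)) {
    stop("invalid parameter: anthropometric fractions must lie in (0, 1)",
         call. = FALSE)
  }
  structure(list(body_mass = body_mass, height = height,
                 shank_mass = shank_mass_frac * body_mass,
                 foot_mass = foot_mass_frac * body_mass,
                 shank_length = shank_length_frac * height,
                 shank_com_frac = shank_com_frac,
                 intercondylar_width = intercondylar_width_frac * height),
            class = "anthropometry")
}

#' One kinematic frame of knee pose
#'
#' Lab-frame convention: x walking direction, y vertical up, z medial
#' (right-knee convention; left limbs are mirrored at ingestion).
#'
#' @param time Time (s).
#' @param flexion_deg,adduction_deg,rotation_deg Knee angles (degrees),
#'   adduction varus-positive.
#' @param kjc Knee joint centre, lab frame (m).
#' @param R_lab 3x3 rotation taking lab-frame vectors into the tibial frame.
#' @return Object of class `"pose_frame"`.
#' @export
pose_frame <- function(time, flexion_deg, adduction_deg, rotation_deg,
                       kjc, R_lab = diag(3)) {
  stopifnot_finite(c(time, flexion_deg, adduction_deg, rotation_deg, kjc,
                     R_lab), "pose frame")
  structure(list(time = time, flexion_deg = flexion_deg,
                 adduction_deg = adduction_deg,
                 rotation_deg = rotation_deg,
                 kjc = as.numeric(kjc), R_lab = R_lab),
            class = "pose_frame")
}

#' One ground-reaction-force frame
#'
#' @param time Time (s).
#' @param force 3D ground reaction force, lab frame (N); vertical component
#'   must be >= 0 during stance.
#' @param cop Centre of pressure, lab frame (m).
#' @param free_moment Free moment about the vertical axis (N m).
#' @return Object of class `"grf_frame"`.
#' @export
grf_frame <- function(time, force, cop, free_moment = 0) {
  stopifnot_finite(c(time, force, cop, free_moment), "GRF frame")
  if (force[2L] < 0) {
    stop("invalid input: vertical GRF must be >= 0 during stance",
         call. = FALSE)
  }
  structure(list(time = time, force = as.numeric(force),
                 cop = as.numeric(cop), free_moment = free_moment),
            class = "grf_frame")
}

#' Quasi-static intersegmental loads at the knee
#'
#' Inertia-free force/moment balance over the foot + shank free body: the
#' net load the femur must deliver at the knee is `-(GRF + segment
#' weights)`, and the net couple is minus the moment of the GRF (about the
#' knee joint centre), segment weights and free moment. Both are expressed
#' in the tibial frame. The external knee adduction moment (EKAM) is the
#' adduction-positive frontal-plane component of the net couple: positive
#' EKAM shifts load toward the medial compartment.
#'
#' @param pose A [pose_frame()].
#' @param grf A [grf_frame()] at the same timestamp.
#' @param anthro An [anthropometry()].
#' @param gravity Gravitational acceleration (m/s^2), default 9.81.
#' @return Object of class `"intersegmental_loads"`: list with `time`,
#'   `force` (N, tibial frame), `moment` (N m, tibial frame) and `ekam`
#'   (N m, adduction-positive).
#' @export
intersegmental_loads <- function(pose, grf, anthro, gravity = 9.81) {
  if (abs(pose$time - grf$time) > 1e-9) {
    stop("alignment error: pose and GRF timestamps differ", call. = FALSE)
  }
  R <- pose$R_lab
  y_tib_lab <- as.numeric(t(R) %*% c(0, 1, 0))  # tibial long axis in lab
  ankle <- pose$kjc - anthro$shank_length * y_tib_lab
  shank_com <- pose$kjc + anthro$shank_com_frac * (ankle - pose$kjc)
  foot_com <- ankle + c(0.03, -0.03, 0)
  w_shank <- c(0, -anthro$shank_mass * gravity, 0)
  w_foot <- c(0, -anthro$foot_mass * gravity, 0)
  f_lab <- -(grf$force + w_shank + w_foot)
  m_lab <- -(cross3(grf$cop - pose$kjc, grf$force) +
               cross3(shank_com - pose$kjc, w_shank) +
               cross3(foot_com - pose$kjc, w_foot) +
               c(0, grf$free_moment, 0))
  f_tib <- as.numeric(R %*% f_lab)
  m_tib <- as.numeric(R %*% m_lab)
  structure(list(time = pose$time, force = f_tib, moment = m_tib,
                 ekam = m_tib[1L]),
            class = "intersegmental_loads")
}

#' Default reduced muscle set (7 elements)
#'
#' Straight-line knee-spanning muscle elements: vasti, rectus femoris,
#' medial/lateral hamstrings, medial/lateral gastrocnemius and tensor
#' fasciae latae / iliotibial band. Proximal points in the femoral frame
#' (carried with the femur by the knee pose) except where noted; distal
#' points in the tibial frame. Coordinates are an idealized condyle-scaled
#' geometry (m); maximal isometric forces are literature-plausible defaults
#' and are scaled per subject (e.g. quadriceps/gastrocnemius weakness).
#'
#' @return Data frame with columns `name`, `f_max` (N), `px, py, pz`
#'   (proximal, femoral frame), `dx, dy, dz` (distal, tibial frame),
#'   classed `"muscle_set"`.
#' @export
default_muscle_set <- function() {
  tab <- read.csv(text = "
name,f_max,px,py,pz,dx,dy,dz
vasti,4000,0.042,0.030,0.000,0.040,-0.045,0.000
rectus_femoris,1200,0.045,0.080,0.000,0.040,-0.045,0.000
hamstrings_med,1500,-0.030,0.090,0.010,-0.015,-0.030,0.030
hamstrings_lat,1200,-0.030,0.090,-0.010,-0.015,-0.040,-0.035
gastroc_med,1400,-0.028,0.005,0.022,-0.040,-0.380,0.010
gastroc_lat,900,-0.028,0.005,-0.022,-0.040,-0.380,-0.010
tfl_itb,600,0.005,0.120,-0.040,0.015,-0.025,-0.035
", stringsAsFactors = FALSE)
  validate_muscle_set(tab)
}

validate_muscle_set <- function(tab) {
  need <- c("name", "f_max", "px", "py", "pz", "dx", "dy", "dz")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    stop("muscle parameter table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(tab$f_max <= 0)) {
    stop("invalid parameter: f_max must be > 0", call. = FALSE)
  }
  class(tab) <- c("muscle_set", "data.frame")
  tab
}

#' Read / write muscle parameters (JSON)
#'
#' One record per muscle element with `name`, `f_max` (N),
#' `proximal_attachment` (femoral frame) and `distal_attachment` (tibial
#' frame) 3-vectors in metres.
#'
#' @param path File path.
#' @return `read_muscle_params()` returns a `"muscle_set"` data frame.
#' @export
read_muscle_params <- function(path) {
  rec <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  prox <- json_mat3(rec$proximal_attachment)
  dist <- json_mat3(rec$distal_attachment)
  validate_muscle_set(data.frame(
    name = rec$name, f_max = rec$f_max,
    px = prox[, 1L], py = prox[, 2L], pz = prox[, 3L],
    dx = dist[, 1L], dy = dist[, 2L], dz = dist[, 3L],
    stringsAsFactors = FALSE))
}

#' @rdname read_muscle_params
#' @param muscles A `"muscle_set"` data frame.
#' @export
write_muscle_params <- function(muscles, path) {
  muscles <- validate_muscle_set(muscles)
  rec <- data.frame(name = muscles$name, f_max = muscles$f_max,
                    stringsAsFactors = FALSE)
  rec$proximal_attachment <- unname(as.matrix(muscles[, c("px", "py", "pz")]))
  rec$distal_attachment <- unname(as.matrix(muscles[, c("dx", "dy", "dz")]))
  jsonlite::write_json(rec, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' Muscle lines of action and moment arms at a pose
#'
#' Places each element's proximal point in the tibial frame via the knee
#' pose, forms the straight-line unit pull direction on the femoral side
#' (from proximal toward distal attachment) and evaluates signed sagittal
#' and frontal moment arms about the knee joint centre (per unit force;
#' sagittal about the medial z axis, frontal about the anterior x axis,
#' adduction-positive).
#'
#' @param pose A [knee_pose()].
#' @param muscles A `"muscle_set"` data frame.
#' @return Data frame with proximal point (`px, py, pz`, tibial frame),
#'   unit direction (`ux, uy, uz`), `r_sag`, `r_front` (m), `name`, `f_max`.
#' @export
muscle_geometry <- function(pose, muscles = default_muscle_set()) {
  if (!inherits(pose, "knee_pose")) {
    stop("configuration error: `pose` must be a knee_pose", call. = FALSE)
  }
  muscles <- validate_muscle_set(muscles)
  prox <- as.matrix(muscles[, c("px", "py", "pz")]) %*% t(pose$R)
  dist <- as.matrix(muscles[, c("dx", "dy", "dz")])
  d <- dist - prox
  len <- sqrt(rowSums(d^2))
  if (any(len < 1e-9)) {
    stop("degenerate geometry: coincident muscle attachments", call. = FALSE)
  }
  u <- d / len
  # per-unit-force moment about the knee centre: m = p x u
  mx <- prox[, 2L] * u[, 3L] - prox[, 3L] * u[, 2L]
  mz <- prox[, 1L] * u[, 2L] - prox[, 2L] * u[, 1L]
  out <- data.frame(name = muscles$name, f_max = muscles$f_max,
                    px = prox[, 1L], py = prox[, 2L], pz = prox[, 3L],
                    ux = u[, 1L], uy = u[, 2L], uz = u[, 3L],
                    r_sag = mz, r_front = mx, stringsAsFactors = FALSE)
  if (any(abs(out$r_sag) >= 0.1) || any(abs(out$r_front) >= 0.1)) {
    stop("invalid geometry: muscle moment arm magnitude must be < 0.1 m",
         call. = FALSE)
  }
  out
}

# Per-muscle KKT solution of the separable recruitment problem at dual
# multipliers (lambda, mu): minimize sum (F/Fmax)^p - s*F over [f_min,f_max]
# with s_i = lambda*r_sag_i + mu*r_front_i.
recruit_forces_at <- function(s, f_max, f_min, p) {
  f <- f_max * ((s * (s > 0)) * f_max / p)^(1 / (p - 1))
  f <- f + (f_min - f) * (f < f_min)
  f - (f - f_max) * (f > f_max)
}

# Single-constraint dual solve: sum(r * F(lambda)) = m with F(lambda) the
# clamped KKT force. h is monotone non-decreasing in lambda, so an
# expanding bracket plus fixed-count bisection is exact to ~1e-16 relative
# and allocation-free enough for the per-frame pipeline loop.
recruit_sagittal_core <- function(m, r, f_max, f_min, p) {
  h <- function(lam) sum(r * recruit_forces_at(lam * r, f_max, f_min, p))
  base <- h(0)
  if (abs(m - base) < 1e-12 * max(1, abs(m))) {
    return(list(forces = recruit_forces_at(0, f_max, f_min, p), lambda = 0))
  }
  dir <- sign(m - base)
  hi <- 1
  repeat {
    if (dir * (h(dir * hi) - m) >= 0 || hi > 1e14) break
    hi <- hi * 8
  }
  lo <- 0; up <- dir * hi
  f_up <- h(up) - m
  if (dir * f_up < 0) {
    # demand unreachable: every recruitable muscle saturated
    return(list(forces = recruit_forces_at(up * r, f_max, f_min, p),
                lambda = up))
  }
  # Illinois false position on the monotone bracket, bisection-safeguarded
  # across the plateaus where every active muscle is clamped.
  f_lo <- base - m
  tol <- 1e-11 * max(1, abs(m))
  lam <- up
  side <- 0L
  for (it in 1:200) {
    lam <- if (abs(f_up - f_lo) > 1e-300) {
      (lo * f_up - up * f_lo) / (f_up - f_lo)
    } else {
      (lo + up) / 2
    }
    if (!is.finite(lam) || lam <= min(lo, up) || lam >= max(lo, up)) {
      lam <- (lo + up) / 2
    }
    fm <- h(lam) - m
    if (abs(fm) < tol || abs(up - lo) < 1e-13 * max(1, abs(lam))) break
    if (dir * fm < 0) {
      lo <- lam; f_lo <- fm
      if (side == -1L) f_up <- f_up / 2
      side <- -1L
    } else {
      up <- lam; f_up <- fm
      if (side == 1L) f_lo <- f_lo / 2
      side <- 1L
    }
  }
  list(forces = recruit_forces_at(lam * r, f_max, f_min, p), lambda = lam)
}

#' Muscle recruitment by static optimization
#'
#' Distributes required knee moments across muscle elements by minimizing
#' the polynomial activation criterion `sum((F_i / f_max_i)^p)` (default
#' cubic, `p = 3`) subject to the sagittal (and optionally frontal) moment
#' equilibrium `sum(r_i * F_i) = M` and bounds
#' `f_min_i <= F_i <= f_max_i`. Solved through the dual: per-muscle forces
#' follow in closed form from the KKT stationarity conditions at given
#' multipliers, and the multipliers are found by a monotone 1-D root search
#' (sagittal only) or a BFGS ascent of the concave dual (both constraints).
#' If the demand is unreachable within the bounds, the remaining moment is
#' assigned to a residual actuator and reported, never silently absorbed.
#'
#' @param m_sag Required sagittal knee moment (N m).
#' @param m_front Optional required frontal knee moment (N m,
#'   adduction-positive); `NULL` (default) recruits against the sagittal
#'   demand only.
#' @param muscles A [muscle_geometry()] data frame (columns `name`,
#'   `f_max`, `r_sag`, `r_front`).
#' @param exponent Polynomial order `p > 1` of the criterion (default 3).
#' @param f_min Optional per-muscle lower force bounds (N), e.g. baseline
#'   forces prescribed by demands at other joints; default 0.
#' @return Object of class `"muscle_forces"`: list with `forces` (named,
#'   N), `activation` (forces / f_max), `residual` (named vector of unmet
#'   sagittal/frontal moment, N m) and the dual multipliers.
#' @export
recruit_muscles <- function(m_sag, m_front = NULL,
                            muscles = muscle_geometry(knee_pose()),
                            exponent = 3, f_min = NULL) {
  if (!is.finite(m_sag) || (!is.null(m_front) && !is.finite(m_front))) {
    stop("invalid input: non-finite required moment", call. = FALSE)
  }
  if (exponent <= 1) {
    stop("invalid parameter: recruitment exponent must be > 1",
         call. = FALSE)
  }
  n <- nrow(muscles)
  if (n == 0L) {
    if (abs(m_sag) > 1e-9 || (!is.null(m_front) && abs(m_front) > 1e-9)) {
      stop("infeasibility error: empty muscle set with nonzero required ",
           "moment", call. = FALSE)
    }
    return(structure(list(forces = numeric(0), activation = numeric(0),
                          residual = c(sag = m_sag,
                                       front = if (is.null(m_front)) 0
                                               else m_front),
                          multipliers = c(0, 0)),
                     class = "muscle_forces"))
  }
  if (is.null(f_min)) f_min <- numeric(n)
  f_min <- pmin(pmax(f_min, 0), muscles$f_max)
  r1 <- muscles$r_sag
  r2 <- if (is.null(m_front)) numeric(n) else muscles$r_front
  p <- exponent

  eval_forces <- function(lam, mu) {
    recruit_forces_at(lam * r1 + mu * r2, muscles$f_max, f_min, p)
  }

  if (is.null(m_front)) {
    sol <- recruit_sagittal_core(m_sag, r1, muscles$f_max, f_min, p)
    forces <- sol$forces
    mult <- c(sag = sol$lambda, front = 0)
  } else {
    neg_dual <- function(th) {
      f <- eval_forces(th[1L], th[2L])
      s <- th[1L] * r1 + th[2L] * r2
      -(sum((f / muscles$f_max)^p - s * f) +
          th[1L] * m_sag + th[2L] * m_front)
    }
    neg_grad <- function(th) {
      f <- eval_forces(th[1L], th[2L])
      c(sum(r1 * f) - m_sag, sum(r2 * f) - m_front)
    }
    fit <- optim(c(0, 0), neg_dual, neg_grad, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-14))
    forces <- eval_forces(fit$par[1L], fit$par[2L])
    mult <- c(sag = fit$par[1L], front = fit$par[2L])
  }
  residual <- c(sag = m_sag - sum(r1 * forces),
                front = if (is.null(m_front)) 0
                        else m_front - sum(r2 * forces))
  structure(list(forces = stats::setNames(forces, muscles$name),
                 activation = stats::setNames(forces / muscles$f_max,
                                              muscles$name),
                 residual = residual, multipliers = mult),
            class = "muscle_forces")
}

#' Assemble the categorized force-source list for one frame
#'
#' Exactly one external source (the net intersegmental knee load: resultant
#' force plus couple at the knee centre), one source per active muscle
#' (straight-line pull on the femoral side of the joint), and the ligament
#' sources passed through.
#'
#' @param pose A [knee_pose()] (used for consistency checking only; muscle
#'   geometry must already be evaluated at this pose).
#' @param loads An [intersegmental_loads()] result.
#' @param muscle_forces A [recruit_muscles()] result.
#' @param muscle_geom The [muscle_geometry()] used for recruitment.
#' @param lig_sources Ligament force-source data frame from
#'   [ligament_sources()] (may have zero rows).
#' @param active_tol Muscles with force below this are dropped (N).
#' @return Force-source data frame ready for [decompose_frame()].
#' @export
assemble_sources <- function(pose, loads, muscle_forces, muscle_geom,
                             lig_sources = NULL, active_tol = 1e-9) {
  if (!inherits(loads, "intersegmental_loads")) {
    stop("`loads` must come from intersegmental_loads()", call. = FALSE)
  }
  ext <- force_source("external", "external", point = c(0, 0, 0),
                      force = loads$force, couple = loads$moment)
  rows <- list(ext)
  if (!is.null(muscle_forces) && length(muscle_forces$forces)) {
    f <- muscle_forces$forces
    active <- which(f > active_tol)
    if (length(active)) {
      g <- muscle_geom[active, , drop = FALSE]
      mus <- data.frame(
        source_id = g$name, category = "muscle",
        px = g$px, py = g$py, pz = g$pz,
        fx = f[active] * g$ux, fy = f[active] * g$uy, fz = f[active] * g$uz,
        cx = 0, cy = 0, cz = 0, stringsAsFactors = FALSE)
      rows <- c(rows, list(mus))
    }
  }
  if (!is.null(lig_sources) && nrow(lig_sources)) {
    rows <- c(rows, list(as_source_table(lig_sources)[,
      c("source_id", "category", "px", "py", "pz",
        "fx", "fy", "fz", "cx", "cy", "cz")]))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
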