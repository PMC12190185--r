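# Canonical trial exchange format: a kinematics CSV (100 Hz), a GRF CSV
# (1000 Hz) and a JSON sidecar with events, anthropometry and subject
# metadata. Column names carry unit suffixes (_s, _deg, _m, _N, _Nm) and
# are validated on read. In memory every trial is held in the right-knee
# convention (z medial, adduction varus-positive); left-limb trials are
# written as recorded (mirrored) and re-mirrored at ingestion.

kin_columns <- c("time_s", "knee_flex_deg", "knee_adduction_deg",
                 "knee_rot_deg", "kjc_x_m", "kjc_y_m", "kjc_z_m",
                 "q_w", "q_x", "q_y", "q_z")
grf_columns <- c("time_s", "fx_N", "fy_N", "fz_N",
                 "cop_x_m", "cop_y_m", "cop_z_m", "tz_Nm")

mirror_quat <- function(q) {
  S <- diag(c(1, 1, -1))
  mat_to_quat(S %*% quat_to_mat(q) %*% S)
}

# Reflect a right/left-knee recording across the sagittal (z = 0) plane.
# Involution: mirroring twice restores the trial.
mirror_trial_data <- function(kin, grf) {
  kin$knee_adduction_deg <- -kin$knee_adduction_deg
  kin$knee_rot_deg <- -kin$knee_rot_deg
  kin$kjc_z_m <- -kin$kjc_z_m
  q <- t(apply(as.matrix(kin[, c("q_w", "q_x", "q_y", "q_z")]), 1L,
               mirror_quat))
  kin$q_w <- q[, 1L]; kin$q_x <- q[, 2L]
  kin$q_y <- q[, 3L]; kin$q_z <- q[, 4L]
  grf$fz_N <- -grf$fz_N
  grf$cop_z_m <- -grf$cop_z_m
  grf$tz_Nm <- -grf$tz_Nm
  list(kin = kin, grf = grf)
}

#' Write / read a gait trial (CSV + JSON sidecar)
#'
#' `write_trial()` writes `<stem>_kinematics.csv`, `<stem>_grf.csv` and
#' `<stem>_meta.json`. Left-limb trials are mirrored back to their
#' as-recorded laterality on write; `read_trial()` mirrors them into the
#' package's right-knee convention, so a written-and-reread trial equals
#' the in-memory original. Numeric columns are written at full double
#' precision.
#'
#' @param trial A `"gait_trial"` (see [generate_trial()]).
#' @param stem Path stem (no extension).
#' @return `write_trial()` returns `stem` invisibly; `read_trial()` returns
#'   a `"gait_trial"`.
#' @export
write_trial <- function(trial, stem) {
  kin <- trial$kin; grf <- trial$grf
  if (identical(trial$limb, "left")) {
    m <- mirror_trial_data(kin, grf)
    kin <- m$kin; grf <- m$grf
  }
  write_csv_full(kin, paste0(stem, "_kinematics.csv"))
  write_csv_full(grf, paste0(stem, "_grf.csv"))
  meta <- list(subject_id = trial$subject_id, group = trial$group,
               limb = trial$limb, trial = trial$trial,
               stance_duration_s = trial$stance_duration,
               events_s = as.list(trial$events),
               body_mass_kg = trial$anthropometry$body_mass,
               height_m = trial$anthropometry$height,
               intercondylar_width_m = trial$geometry$width,
               speed_m_per_s = trial$speed,
               strength_scale_quad = trial$strength_scale_quad,
               strength_scale_gastroc = trial$strength_scale_gastroc,
               seed = trial$seed,
               convention = "as_recorded")
  jsonlite::write_json(meta, paste0(stem, "_meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(stem)
}

check_columns <- function(df, expected, file) {
  for (col in expected) {
    if (!col %in% names(df)) {
      stop("schema error in ", file, ": missing column `", col,
           "` (unit-suffixed names are required)", call. = FALSE)
    }
  }
  invisible(df)
}

#' @rdname write_trial
#' @export
read_trial <- function(stem) {
  kin_path <- paste0(stem, "_kinematics.csv")
  grf_path <- paste0(stem, "_grf.csv")
  meta_path <- paste0(stem, "_meta.json")
  for (p in c(kin_path, grf_path, meta_path)) {
    if (!file.exists(p)) stop("schema error: missing file ", p,
                              call. = FALSE)
  }
  kin <- read.csv(kin_path)
  grf <- read.csv(grf_path)
  check_columns(kin, kin_columns, basename(kin_path))
  check_columns(grf, grf_columns, basename(grf_path))
  kin[] <- lapply(kin, as.numeric)   # all-zero columns parse as integer
  grf[] <- lapply(grf, as.numeric)
  meta <- jsonlite::fromJSON(meta_path)
  ev <- unlist(meta$events_s)
  if (is.unsorted(ev[c("hs_ipsi", "to_contra", "hs_contra", "to_ipsi")],
                  strictly = TRUE)) {
    stop("schema error: events must be ordered hs_ipsi < to_contra < ",
         "hs_contra < to_ipsi", call. = FALSE)
  }
  if (any(grf$fy_N < -1e-9)) {
    stop("schema error: vertical GRF (fy_N) must be >= 0 during stance",
         call. = FALSE)
  }
  if (identical(meta$limb, "left") &&
      identical(meta$convention, "as_recorded")) {
    m <- mirror_trial_data(kin, grf)
    kin <- m$kin; grf <- m$grf
  }
  anthro <- anthropometry(meta$body_mass_kg, meta$height_m)
  structure(list(subject_id = meta$subject_id, group = meta$group,
                 limb = meta$limb, trial = meta$trial,
                 stance_duration = meta$stance_duration_s,
                 events = ev, kin = kin, grf = grf,
                 anthropometry = anthro,
                 geometry = contact_geometry(meta$intercondylar_width_m),
                 speed = meta$speed_m_per_s,
                 strength_scale_quad = meta$strength_scale_quad,
                 strength_scale_gastroc = meta$strength_scale_gastroc,
                 seed = meta$seed),
            class = "gait_trial")
}
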