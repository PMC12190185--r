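#' Two-point tibiofemoral contact geometry
#'
#' The joint transmits axial load through one medial and one lateral contact
#' point; their frontal-plane separation (the intercondylar width `w`) is
#' the lever arm of the moment-balance load split. Geometry is fixed per
#' subject. Axes default to the canonical tibial frame: longitudinal axis
#' proximal-positive, anterior-posterior axis as the frontal-plane moment
#' axis (adduction-positive).
#'
#' @param width Intercondylar width (m), > 0. Used to place the default
#'   contact points at `z = +/- width/2`.
#' @param medial_cp,lateral_cp Contact points, 3-vectors (m), tibial frame.
#' @param axial_axis Unit vector of the tibial longitudinal axis,
#'   proximal-positive.
#' @param ap_axis Unit anterior-posterior axis (frontal moment axis).
#' @return Object of class `"contact_geometry"`.
#' @export
contact_geometry <- function(width = 0.046,
                             medial_cp = c(0, 0, width / 2),
                             lateral_cp = c(0, 0, -width / 2),
                             axial_axis = c(0, 1, 0),
                             ap_axis = c(1, 0, 0)) {
  stopifnot_finite(c(medial_cp, lateral_cp, axial_axis, ap_axis),
                   "contact geometry")
  sep <- medial_cp - lateral_cp
  w <- vnorm(sep - sum(sep * axial_axis) * axial_axis -
               sum(sep * ap_axis) * ap_axis)
  if (w <= 1e-6) {
    stop("degenerate geometry: contact points have no frontal-plane ",
         "separation", call. = FALSE)
  }
  if (abs(vnorm(axial_axis) - 1) > 1e-9 || abs(vnorm(ap_axis) - 1) > 1e-9 ||
      abs(sum(axial_axis * ap_axis)) > 1e-9) {
    stop("invalid geometry: axial_axis and ap_axis must be orthonormal",
         call. = FALSE)
  }
  structure(list(medial_cp = as.numeric(medial_cp),
                 lateral_cp = as.numeric(lateral_cp),
                 width = w,
                 axial_axis = as.numeric(axial_axis),
                 ap_axis = as.numeric(ap_axis)),
            class = "contact_geometry")
}

#' Construct a force source
#'
#' One categorized joint-crossing force line of action in the tibial frame,
#' expressed in the on-femur convention (the load delivered to the joint
#' from the femoral side; see the package overview). Only external sources
#' may carry a free couple.
#'
#' @param source_id Short identifier.
#' @param category One of `"external"`, `"muscle"`, `"ligament"`.
#' @param point Application point, 3-vector (m).
#' @param force Force vector, 3-vector (N).
#' @param couple Optional free moment, 3-vector (N m); external only.
#' @return One-row force-source data frame with columns `source_id`,
#'   `category`, `px, py, pz`, `fx, fy, fz`, `cx, cy, cz`.
#' @export
force_source <- function(source_id, category, point, force,
                         couple = c(0, 0, 0)) {
  category <- match.arg(category, c("external", "muscle", "ligament"))
  stopifnot_finite(c(point, force, couple), "force source")
  if (category != "external" && any(couple != 0)) {
    stop("only external sources may carry a free couple", call. = FALSE)
  }
  data.frame(source_id = source_id, category = category,
             px = point[1L], py = point[2L], pz = point[3L],
             fx = force[1L], fy = force[2L], fz = force[3L],
             cx = couple[1L], cy = couple[2L], cz = couple[3L],
             stringsAsFactors = FALSE)
}

as_source_table <- function(sources) {
  need <- c("source_id", "category", "px", "py", "pz",
            "fx", "fy", "fz", "cx", "cy", "cz")
  missing_cols <- setdiff(need, names(sources))
  if (length(missing_cols)) {
    stop("source table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  sources
}

#' Axial (longitudinal-tibia) component of a force source
#'
#' Only the contact load along the tibial longitudinal axis is decomposed;
#' the projection is compressive-positive: a load pushing the femur onto
#' the tibia (anti-parallel to the proximal-positive axis) is positive.
#'
#' @param src A one-row force-source data frame (see [force_source()]).
#' @param geom A [contact_geometry()].
#' @return Axial load in newtons.
#' @export
axial_component <- function(src, geom) {
  src <- as_source_table(src)
  -(src$fx * geom$axial_axis[1L] + src$fy * geom$axial_axis[2L] +
      src$fz * geom$axial_axis[3L])
}

#' Frontal-plane moment of a force source about a point
#'
#' Component about the anterior-posterior axis, through `point`, of
#' `r x F + couple`. Adduction-positive: a positive moment loads the medial
#' compartment.
#'
#' @inheritParams axial_component
#' @param point Reference point, 3-vector (m), tibial frame.
#' @return Moment in newton-metres (vectorized over rows of `src`).
#' @export
frontal_moment_about <- function(src, point, geom) {
  src <- as_source_table(src)
  rx <- src$px - point[1L]; ry <- src$py - point[2L]; rz <- src$pz - point[3L]
  mx <- ry * src$fz - rz * src$fy + src$cx
  my <- rz * src$fx - rx * src$fz + src$cy
  mz <- rx * src$fy - ry * src$fx + src$cz
  mx * geom$ap_axis[1L] + my * geom$ap_axis[2L] + mz * geom$ap_axis[3L]
}

#' Decompose one frame of force sources into compartment contact loads
#'
#' Quasi-static frontal-plane moment balance over the two-point contact:
#' each source's medial contribution is its frontal moment about the lateral
#' contact point divided by the intercondylar width,
#' `C_med = M(lateral_cp) / w`; its total contribution is its axial
#' component, and `C_lat = C_tot - C_med`. The decomposition is additive
#' (exactly linear in the sources), and per-source contributions may be
#' negative - a negative value means that source unloads that compartment.
#'
#' @param sources Force-source data frame, one row per source (>= 1 row).
#' @param geom A [contact_geometry()].
#' @return Object of class `"frame_decomposition"`: a list with
#'   `per_source` (data frame `source_id`, `category`, `c_med`, `c_lat`,
#'   `c_tot` in N), `by_category` (sums for external/muscle/ligament), and
#'   totals `f_med`, `f_lat`, `f_total`.
#' @export
decompose_frame <- function(sources, geom) {
  sources <- as_source_table(sources)
  if (nrow(sources) < 1L) {
    stop("empty input: need at least one force source", call. = FALSE)
  }
  if (geom$width <= 1e-6) {
    stop("degenerate geometry: intercondylar width too small", call. = FALSE)
  }
  a <- axial_component(sources, geom)
  m_lat <- frontal_moment_about(sources, geom$lateral_cp, geom)
  c_med <- m_lat / geom$width
  c_lat <- a - c_med
  per_source <- data.frame(source_id = sources$source_id,
                           category = sources$category,
                           c_med = c_med, c_lat = c_lat, c_tot = a,
                           stringsAsFactors = FALSE)
  cats <- c("external", "muscle", "ligament")
  by_category <- data.frame(
    category = cats,
    c_med = vapply(cats, function(k) sum(c_med[sources$category == k]), 0),
    c_lat = vapply(cats, function(k) sum(c_lat[sources$category == k]), 0),
    c_tot = vapply(cats, function(k) sum(a[sources$category == k]), 0),
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(list(per_source = per_source, by_category = by_category,
                 f_med = sum(c_med), f_lat = sum(c_lat), f_total = sum(a)),
            class = "frame_decomposition")
}

#' Decompose a time series of frames
#'
#' Frame-wise application of [decompose_frame()] carrying the time vector
#' through. The per-category streams are returned in long and wide form for
#' downstream phase integration.
#'
#' @param frames List of force-source data frames, time-ordered.
#' @param geom A [contact_geometry()].
#' @param time Numeric vector of frame times (s), same length as `frames`.
#' @return Object of class `"decomposition_series"`: list with `time` and
#'   `by_category`, a data frame with one row per frame holding columns
#'   `<category>_med`, `<category>_lat`, `<category>_tot` plus totals
#'   `f_med`, `f_lat`, `f_total`.
#' @export
decompose_trial <- function(frames, geom, time = seq_along(frames) - 1) {
  if (length(frames) == 0L) {
    stop("empty input: trial has no frames", call. = FALSE)
  }
  if (length(time) != length(frames)) {
    stop("alignment error: time vector and frame list differ in length",
         call. = FALSE)
  }
  if (is.unsorted(time, strictly = TRUE)) {
    stop("invalid input: frames must be strictly time-ordered",
         call. = FALSE)
  }
  rows <- lapply(frames, function(fr) {
    d <- decompose_frame(fr, geom)
    b <- d$by_category
    stats::setNames(
      c(b$c_med, b$c_lat, b$c_tot, d$f_med, d$f_lat, d$f_total),
      c(paste0(b$category, "_med"), paste0(b$category, "_lat"),
        paste0(b$category, "_tot"), "f_med", "f_lat", "f_total"))
  })
  by_category <- as.data.frame(do.call(rbind, rows))
  structure(list(time = as.numeric(time), by_category = by_category),
            class = "decomposition_series")
}

#' Write / read a decomposition series (CSV)
#'
#' Long format, one row per frame and category, columns `time_s`,
#' `category`, `c_med_N`, `c_lat_N`, `c_tot_N`; the totals stream is
#' appended under category `"total"`. The round trip is bit-exact (values
#' are printed at full double precision).
#'
#' @param series A `"decomposition_series"` from [decompose_trial()].
#' @param path CSV file path.
#' @return `write_decomposition()` returns `path` invisibly;
#'   `read_decomposition()` returns the series.
#' @export
write_decomposition <- function(series, path) {
  bc <- series$by_category
  cats <- c("external", "muscle", "ligament")
  long <- do.call(rbind, lapply(cats, function(k) {
    data.frame(time_s = series$time, category = k,
               c_med_N = bc[[paste0(k, "_med")]],
               c_lat_N = bc[[paste0(k, "_lat")]],
               c_tot_N = bc[[paste0(k, "_tot")]],
               stringsAsFactors = FALSE)
  }))
  long <- rbind(long, data.frame(time_s = series$time, category = "total",
                                 c_med_N = bc$f_med, c_lat_N = bc$f_lat,
                                 c_tot_N = bc$f_total,
                                 stringsAsFactors = FALSE))
  write_csv_full(long, path)
  invisible(path)
}

#' @rdname write_decomposition
#' @export
read_decomposition <- function(path) {
  long <- read.csv(path, stringsAsFactors = FALSE)
  num <- setdiff(names(long), "category")
  long[num] <- lapply(long[num], as.numeric)
  tot <- long[long$category == "total", ]
  time <- tot$time_s
  bc <- data.frame(row.names = seq_along(time))
  for (k in c("external", "muscle", "ligament")) {
    sub <- long[long$category == k, ]
    bc[[paste0(k, "_med")]] <- sub$c_med_N
    bc[[paste0(k, "_lat")]] <- sub$c_lat_N
    bc[[paste0(k, "_tot")]] <- sub$c_tot_N
  }
  bc$f_med <- tot$c_med_N; bc$f_lat <- tot$c_lat_N; bc$f_total <- tot$c_tot_N
  structure(list(time = time, by_category = bc),
            class = "decomposition_series")
}

# CSV writer that preserves full double precision (bit-exact round trip).
write_csv_full <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE)
  out <- df
  out[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
}
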