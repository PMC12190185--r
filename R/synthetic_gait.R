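# Seeded synthetic stance-phase gait generator. The cohort templates encode
# the study conditions: two groups of older adults, a healthy-like group and
# a medial-KOA-like group whose gait differs only through interpretable
# parameters (larger knee adduction moment lever, varus offset, weaker
# quadriceps/gastrocnemius, slower walking speed). Waveform shapes are
# standard adult stance templates; no attempt is made to tune them to any
# published contribution percentages.

with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Low-pass filtered Gaussian perturbation: white noise convolved with a
# Gaussian kernel whose width is given in seconds, rescaled to preserve the
# requested marginal SD. Smooth noise keeps the quasi-static assumption
# valid (no high-frequency content to differentiate).
smooth_noise <- function(n, sd, fs, width_s = 0.05) {
  if (sd <= 0 || n < 2L) return(numeric(n))
  ks <- max(1, width_s * fs)
  half <- ceiling(3 * ks)
  kernel <- exp(-0.5 * ((-half:half) / ks)^2)
  kernel <- kernel / sqrt(sum(kernel^2))
  x <- rnorm(n + 2L * half)
  as.numeric(stats::filter(x, kernel, sides = 2L))[(half + 1L):(half + n)] * sd
}

smoothstep <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u * u * (3 - 2 * u)
}

#' Cohort template: the study conditions of one group
#'
#' Parameter distributions from which synthetic subjects are drawn. The two
#' presets emulate older-adult cohorts: `"healthy"` and `"koa"`
#' (medial knee osteoarthritis), the latter differing through a larger knee
#' adduction moment lever arm, a varus alignment offset, weakened
#' quadriceps and gastrocnemius, and slower self-selected walking speed.
#'
#' @param group `"healthy"` or `"koa"`; selects the preset defaults.
#' @param n_subjects Number of subjects (default 20 per group).
#' @param trials_per_limb Successful trials per limb (default 10).
#' @param speed_mean,speed_sd Walking speed (m/s).
#' @param mass_mean,mass_sd Body mass (kg).
#' @param height_mean,height_sd Stature (m).
#' @param ekam_scale Multiplier on the frontal-plane lever arm of the
#'   ground reaction force (dimensionless).
#' @param varus_offset_deg Group varus alignment offset (degrees).
#' @param strength_scale_quad,strength_scale_gastroc Maximal-force scale
#'   factors in (0, 1] applied to the quadriceps / gastrocnemius elements.
#' @param noise_sd List with `angle_deg`, `grf_frac`, `cop_m`: smooth-noise
#'   SDs for joint angles, GRF amplitude fraction, and centre of pressure.
#' @param seed Master seed; the whole cohort is a pure function of the
#'   template including this seed.
#' @return Object of class `"cohort_template"`.
#' @export
cohort_template <- function(group = c("healthy", "koa"),
                            n_subjects = 20L,
                            trials_per_limb = 10L,
                            speed_mean = NULL, speed_sd = NULL,
                            mass_mean = NULL, mass_sd = NULL,
                            height_mean = NULL, height_sd = NULL,
                            ekam_scale = NULL,
                            varus_offset_deg = NULL,
                            strength_scale_quad = NULL,
                            strength_scale_gastroc = NULL,
                            noise_sd = list(angle_deg = 0.5,
                                            grf_frac = 0.02,
                                            cop_m = 0.002),
                            seed = 0L) {
  group <- match.arg(group)
  preset <- if (group == "healthy") {
    list(speed_mean = 1.20, speed_sd = 0.10, mass_mean = 65.7,
         mass_sd = 4.6, height_mean = 1.58, height_sd = 0.05,
         ekam_scale = 1.0, varus_offset_deg = 0.5,
         strength_scale_quad = 1.0, strength_scale_gastroc = 1.0)
  } else {
    list(speed_mean = 0.90, speed_sd = 0.12, mass_mean = 66.8,
         mass_sd = 8.7, height_mean = 1.56, height_sd = 0.06,
         ekam_scale = 1.4, varus_offset_deg = 5.0,
         strength_scale_quad = 0.7, strength_scale_gastroc = 0.7)
  }
  pick <- function(x, d) if (is.null(x)) d else x
  tpl <- list(group = group,
              n_subjects = as.integer(n_subjects),
              trials_per_limb = as.integer(trials_per_limb),
              speed_mean = pick(speed_mean, preset$speed_mean),
              speed_sd = pick(speed_sd, preset$speed_sd),
              mass_mean = pick(mass_mean, preset$mass_mean),
              mass_sd = pick(mass_sd, preset$mass_sd),
              height_mean = pick(height_mean, preset$height_mean),
              height_sd = pick(height_sd, preset$height_sd),
              ekam_scale = pick(ekam_scale, preset$ekam_scale),
              varus_offset_deg = pick(varus_offset_deg,
                                      preset$varus_offset_deg),
              strength_scale_quad = pick(strength_scale_quad,
                                         preset$strength_scale_quad),
              strength_scale_gastroc = pick(strength_scale_gastroc,
                                            preset$strength_scale_gastroc),
              noise_sd = noise_sd,
              seed = as.integer(seed))
  if (tpl$n_subjects < 1L || tpl$trials_per_limb < 1L) {
    stop("invalid template: n_subjects and trials_per_limb must be >= 1",
         call. = FALSE)
  }
  if (tpl$ekam_scale <= 0 || tpl$strength_scale_quad <= 0 ||
      tpl$strength_scale_quad > 1 || tpl$strength_scale_gastroc <= 0 ||
      tpl$strength_scale_gastroc > 1) {
    stop("invalid template: scales must be > 0 and strength scales <= 1",
         call. = FALSE)
  }
  class(tpl) <- "cohort_template"
  tpl
}

#' Subject parameters for the synthetic generator
#'
#' @param subject_id Identifier.
#' @param body_mass,height Anthropometry (kg, m).
#' @param speed Walking speed (m/s), > 0.
#' @param varus_deg Subject baseline varus alignment (degrees),
#'   adduction-positive.
#' @param ekam_scale Frontal lever-arm multiplier.
#' @param strength_scale_quad,strength_scale_gastroc Muscle strength
#'   scale factors in (0, 1].
#' @param noise_sd Noise SD list (see [cohort_template()]).
#' @param group Group label carried through to summaries.
#' @return List of class `"gait_subject"`.
#' @export
gait_subject <- function(subject_id, body_mass = 66, height = 1.57,
                         speed = 1.1, varus_deg = 1,
                         ekam_scale = 1,
                         strength_scale_quad = 1,
                         strength_scale_gastroc = 1,
                         noise_sd = list(angle_deg = 0.5, grf_frac = 0.02,
                                         cop_m = 0.002),
                         group = "healthy") {
  if (speed <= 0) {
    stop("invalid parameter: speed must be > 0", call. = FALSE)
  }
  structure(list(subject_id = subject_id, body_mass = body_mass,
                 height = height, speed = speed, varus_deg = varus_deg,
                 ekam_scale = ekam_scale,
                 strength_scale_quad = strength_scale_quad,
                 strength_scale_gastroc = strength_scale_gastroc,
                 noise_sd = noise_sd, group = group),
            class = "gait_subject")
}

# Noiseless template values, exposed for tests: vertical GRF shape (per
# body weight) and its mid-stance value.
grf_vertical_template <- function(tbar) {
  (0.75 / 0.65) * (sin(pi * tbar) + 0.35 * sin(3 * pi * tbar))
}

#' Generate one synthetic stance-phase gait trial
#'
#' Deterministic for a given subject and seed. The vertical ground reaction
#' force follows a smooth two-peak stance template (peaks about 1.1 body
#' weight, mid-stance valley exactly 0.75 body weight before noise, zero at
#' both stance endpoints); the anterior-posterior force is derived by
#' prescribing the sagittal offset of the GRF line of action from the knee
#' (posterior early in stance, anterior late); the centre of pressure
#' progresses heel to toe with a medial offset (scaled by the subject's
#' `ekam_scale`) that creates the external knee adduction moment; knee
#' flexion follows a standard stance pattern and the varus angle is the
#' subject baseline plus a smooth within-stance modulation. Kinematics are
#' sampled at 100 Hz and GRF at 1000 Hz. Gait events are placed at
#' configurable stance fractions (defaults 16% / 84%).
#'
#' @param subject A [gait_subject()].
#' @param seed Integer seed for the trial's smooth noise.
#' @param limb `"right"` or `"left"` (data are always held in the
#'   right-knee convention; the label controls mirroring on write).
#' @param trial Trial index (bookkeeping).
#' @param ds_fractions Double-support boundaries as fractions of stance.
#' @param stance_duration Optional stance duration override (s), > 0;
#'   default derived from walking speed.
#' @return Object of class `"gait_trial"`: kinematics and GRF data frames,
#'   events, anthropometry, contact geometry and subject metadata.
#' @export
generate_trial <- function(subject, seed = 0L, limb = "right", trial = 1L,
                           ds_fractions = c(0.16, 0.84),
                           stance_duration = NULL) {
  if (!inherits(subject, "gait_subject")) subject <- do.call(gait_subject,
                                                             subject)
  if (is.null(stance_duration)) {
    stance_duration <- 0.78 / subject$speed
  }
  if (!is.finite(stance_duration) || stance_duration <= 0) {
    stop("invalid parameter: stance duration must be > 0", call. = FALSE)
  }
  # snap to the 100 Hz grid so both sampling clocks hit the endpoints
  T <- max(0.1, round(stance_duration * 100) / 100)
  ns <- subject$noise_sd
  bw <- subject$body_mass * 9.81
  anthro <- anthropometry(subject$body_mass, subject$height)
  L <- anthro$shank_length
  kin_t <- seq(0, T, by = 0.01)
  grf_t <- seq(0, T, by = 0.001)

  with_seed(seed, {
    # --- kinematics (100 Hz) -------------------------------------------
    tb <- kin_t / T
    flex <- 6 + 12 * exp(-((tb - 0.15) / 0.10)^2) + 30 * tb^5 +
      smooth_noise(length(tb), ns$angle_deg, 100)
    varus <- subject$varus_deg - 1.5 * sin(pi * tb) +
      smooth_noise(length(tb), ns$angle_deg, 100)
    introt <- 2 * sin(2 * pi * tb) +
      smooth_noise(length(tb), ns$angle_deg, 100)
    kjc_x <- 0.10 * sin(pi * (tb - 0.5))
    phi <- asin(pmin(pmax(kjc_x / L, -1), 1))   # shank forward tilt
    kjc_y <- 0.08 + L * cos(phi)
    kjc_z <- rep(0, length(tb))
    quat <- t(vapply(phi, function(p) mat_to_quat(rot_z(p)),
                     numeric(4L)))
    kin <- data.frame(time_s = kin_t,
                      knee_flex_deg = flex,
                      knee_adduction_deg = varus,
                      knee_rot_deg = introt,
                      kjc_x_m = kjc_x, kjc_y_m = kjc_y, kjc_z_m = kjc_z,
                      q_w = quat[, 1L], q_x = quat[, 2L],
                      q_y = quat[, 3L], q_z = quat[, 4L])

    # --- ground reaction forces (1000 Hz) ------------------------------
    tg <- grf_t / T
    fv <- bw * grf_vertical_template(tg) *
      (1 + smooth_noise(length(tg), ns$grf_frac, 1000))
    fv <- pmax(fv, 0)
    cop_x <- -0.05 + 0.17 * smoothstep(tg) +
      smooth_noise(length(tg), ns$cop_m, 1000)
    lever <- 0.035 * subject$ekam_scale
    cop_z <- lever + smooth_noise(length(tg), ns$cop_m, 1000)
    # sagittal offset of the GRF line from the knee at knee height:
    # posterior early (quadriceps demand), anterior late (gastrocnemius)
    o_amp <- 0.05 * sqrt(subject$speed / 1.2)
    o <- -o_amp * sin(2 * pi * tg)
    kjc_x_g <- 0.10 * sin(pi * (tg - 0.5))
    kjc_y_g <- 0.08 + L * cos(asin(pmin(pmax(kjc_x_g / L, -1), 1)))
    fx <- fv * (kjc_x_g + o - cop_x) / kjc_y_g
    fz <- -0.02 * bw * sin(pi * tg) *
      (1 + smooth_noise(length(tg), ns$grf_frac, 1000))
    grf <- data.frame(time_s = grf_t, fx_N = fx, fy_N = fv, fz_N = fz,
                      cop_x_m = cop_x, cop_y_m = 0, cop_z_m = cop_z,
                      tz_Nm = 0)
  })

  events <- c(hs_ipsi = 0, to_contra = ds_fractions[1L] * T,
              hs_contra = ds_fractions[2L] * T, to_ipsi = T)
  structure(list(subject_id = subject$subject_id, group = subject$group,
                 limb = limb, trial = trial,
                 stance_duration = T, events = events,
                 kin = kin, grf = grf,
                 anthropometry = anthro,
                 geometry = contact_geometry(anthro$intercondylar_width),
                 speed = subject$speed,
                 strength_scale_quad = subject$strength_scale_quad,
                 strength_scale_gastroc = subject$strength_scale_gastroc,
                 seed = seed),
            class = "gait_trial")
}

#' Generate a two-limb, multi-trial synthetic cohort
#'
#' Draws between-subject parameters once per subject from the template
#' distributions, then generates `n_subjects * 2 limbs * trials_per_limb`
#' stance trials with deterministically derived child seeds. The whole
#' cohort is a pure function of the template (including its seed).
#'
#' @param template A [cohort_template()].
#' @return List with `trials` (list of [generate_trial()] results) and
#'   `subjects` (one-row-per-subject parameter table).
#' @export
generate_cohort <- function(template) {
  if (!inherits(template, "cohort_template")) {
    stop("invalid template: use cohort_template()", call. = FALSE)
  }
  n <- template$n_subjects
  with_seed(template$seed, {
    subjects <- data.frame(
      subject_id = sprintf("%s%02d", substr(template$group, 1L, 1L),
                           seq_len(n)),
      group = template$group,
      body_mass = pmax(40, rnorm(n, template$mass_mean, template$mass_sd)),
      height = pmax(1.3, rnorm(n, template$height_mean,
                               template$height_sd)),
      speed = pmax(0.4, rnorm(n, template$speed_mean, template$speed_sd)),
      varus_deg = template$varus_offset_deg + rnorm(n, 0, 1),
      ekam_scale = template$ekam_scale * pmax(0.5, rnorm(n, 1, 0.08)),
      strength_scale_quad = template$strength_scale_quad,
      strength_scale_gastroc = template$strength_scale_gastroc,
      stringsAsFactors = FALSE
    )
    trial_seeds <- matrix(sample.int(2^30, n * 2L * template$trials_per_limb),
                          nrow = n)
    speed_jitter <- matrix(rnorm(n * 2L * template$trials_per_limb, 1, 0.02),
                           nrow = n)
  })
  trials <- vector("list", n * 2L * template$trials_per_limb)
  idx <- 0L
  for (i in seq_len(n)) {
    col <- 0L
    for (limb in c("right", "left")) {
      for (k in seq_len(template$trials_per_limb)) {
        col <- col + 1L
        subj <- gait_subject(
          subject_id = subjects$subject_id[i],
          body_mass = subjects$body_mass[i],
          height = subjects$height[i],
          speed = subjects$speed[i] * speed_jitter[i, col],
          varus_deg = subjects$varus_deg[i],
          ekam_scale = subjects$ekam_scale[i],
          strength_scale_quad = subjects$strength_scale_quad[i],
          strength_scale_gastroc = subjects$strength_scale_gastroc[i],
          noise_sd = template$noise_sd,
          group = template$group)
        idx <- idx + 1L
        trials[[idx]] <- generate_trial(subj, seed = trial_seeds[i, col],
                                        limb = limb, trial = k)
      }
    }
  }
  list(trials = trials, subjects = subjects, template = template)
}
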