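#' Run the decomposition engine over one gait trial
#'
#' Per kinematic frame: evaluates ligament bundle forces at the knee pose,
#' computes the quasi-static intersegmental knee load from the (10 ms
#' window-averaged) GRF, recruits muscle forces against the sagittal knee
#' moment remaining after the pose-determined ligament moments - with the
#' two-joint gastrocnemius carrying an ankle-plantarflexion-demand baseline
#' force - assembles the categorized force sources and decomposes them into
#' medial/lateral/total axial contact-load contributions.
#'
#' Contact is unilateral: condyles can push but not pull. Whenever the
#' passive plus sagittally recruited solution would put a compartment in
#' tension, recruitment is repeated with an additional frontal
#' compartment-load constraint that holds the unloading compartment at a
#' marginal compressive load of 1% body weight, the same role contact
#' elements that cannot pull play in full musculoskeletal pipelines.
#'
#' @param trial A `"gait_trial"`.
#' @param ligaments Calibrated [ligament_set()]; `NULL` disables ligaments.
#' @param muscles `"muscle_set"` table; `NULL` disables muscles.
#' @param recruitment_exponent Polynomial order of the recruitment
#'   criterion (default 3).
#' @param gastroc_share Fraction of the ankle plantarflexion demand carried
#'   by the gastrocnemius pair (default 0.35).
#' @param ankle_arm Achilles moment arm at the ankle (m, default 0.05).
#' @param gravity m/s^2.
#' @return Object of class `"trial_result"`: the `"decomposition_series"`
#'   in `$series`, plus `$ekam` (N m), `$muscle_forces` (frames x muscles,
#'   N), `$residual` (max |unmet sagittal moment|, N m) and trial metadata.
#' @export
run_trial <- function(trial, ligaments = default_ligament_params(),
                      muscles = default_muscle_set(),
                      recruitment_exponent = 3,
                      gastroc_share = 0.35, ankle_arm = 0.05,
                      gravity = 9.81) {
  kin <- trial$kin
  grf <- trial$grf
  anthro <- trial$anthropometry
  geom <- trial$geometry
  nk <- nrow(kin)

  # GRF decimation: average the surrounding 10 ms window onto the 100 Hz
  # kinematic clock.
  idx <- round(grf$time_s * 100) + 1L
  counts <- tabulate(idx, nbins = nk)
  dec <- function(x) as.numeric(rowsum(x, idx)) / counts
  g_fx <- dec(grf$fx_N); g_fy <- dec(grf$fy_N); g_fz <- dec(grf$fz_N)
  g_cx <- dec(grf$cop_x_m); g_cy <- dec(grf$cop_y_m)
  g_cz <- dec(grf$cop_z_m); g_tz <- dec(grf$tz_Nm)

  # per-trial muscle strength scaling (quadriceps / gastrocnemius)
  mus <- muscles
  if (!is.null(mus)) {
    mus <- validate_muscle_set(mus)
    quad <- mus$name %in% c("vasti", "rectus_femoris")
    gas <- mus$name %in% c("gastroc_med", "gastroc_lat")
    mus$f_max[quad] <- mus$f_max[quad] * trial$strength_scale_quad
    mus$f_max[gas] <- mus$f_max[gas] * trial$strength_scale_gastroc
    gas_idx <- which(gas)
    gas_split <- mus$f_max[gas_idx] / sum(mus$f_max[gas_idx])
    mus_prox0 <- as.matrix(mus[, c("px", "py", "pz")])
    mus_dist <- as.matrix(mus[, c("dx", "dy", "dz")])
    mus_fmax <- mus$f_max
  }
  if (!is.null(ligaments)) {
    lig_fem0 <- as.matrix(ligaments[, c("fx", "fy", "fz")])
    lig_tib <- as.matrix(ligaments[, c("tx", "ty", "tz")])
    lig_l0 <- ligaments$zero_load_length
    lig_k <- ligaments$k
    lig_elim <- ligaments$eps_lim
  }

  axial <- geom$axial_axis; ap <- geom$ap_axis
  lat_cp <- geom$lateral_cp; w <- geom$width
  cats <- c("external", "muscle", "ligament")
  ncols <- c("external_med", "muscle_med", "ligament_med",
             "external_lat", "muscle_lat", "ligament_lat",
             "external_tot", "muscle_tot", "ligament_tot",
             "f_med", "f_lat", "f_total")
  out <- matrix(0, nk, length(ncols), dimnames = list(NULL, ncols))
  ekam <- numeric(nk)
  mf <- if (is.null(mus)) NULL else
    matrix(0, nk, nrow(mus), dimnames = list(NULL, mus$name))
  resid_max <- 0

  w_shank <- c(0, -anthro$shank_mass * gravity, 0)
  w_foot <- c(0, -anthro$foot_mass * gravity, 0)

  for (i in seq_len(nk)) {
    R <- rot_x(deg2rad(kin$knee_adduction_deg[i])) %*%
      rot_z(-deg2rad(kin$knee_flex_deg[i])) %*%
      rot_y(deg2rad(kin$knee_rot_deg[i]))
    R_lab <- quat_to_mat(c(kin$q_w[i], kin$q_x[i], kin$q_y[i], kin$q_z[i]))
    kjc <- c(kin$kjc_x_m[i], kin$kjc_y_m[i], kin$kjc_z_m[i])
    f_grf <- c(g_fx[i], g_fy[i], g_fz[i])
    cop <- c(g_cx[i], g_cy[i], g_cz[i])

    # quasi-static intersegmental knee load (tibial frame)
    y_tib_lab <- c(R_lab[2L, 1L], R_lab[2L, 2L], R_lab[2L, 3L])
    ankle <- kjc - anthro$shank_length * y_tib_lab
    shank_com <- kjc + anthro$shank_com_frac * (ankle - kjc)
    foot_com <- ankle + c(0.03, -0.03, 0)
    f_lab <- -(f_grf + w_shank + w_foot)
    m_lab <- -(cross3(cop - kjc, f_grf) +
                 cross3(shank_com - kjc, w_shank) +
                 cross3(foot_com - kjc, w_foot) + c(0, g_tz[i], 0))
    ext_f <- as.numeric(R_lab %*% f_lab)
    ext_m <- as.numeric(R_lab %*% m_lab)
    ekam[i] <- ext_m[1L]

    lig_mz <- 0
    if (!is.null(ligaments)) {
      fem <- lig_fem0 %*% t(R)
      d <- lig_tib - fem
      len <- sqrt(rowSums(d * d))
      lig_force <- bundle_force((len - lig_l0) / lig_l0, lig_k, lig_elim)
      lf <- d / len * lig_force
      lig_mz <- sum(fem[, 1L] * lf[, 2L] - fem[, 2L] * lf[, 1L])
    }

    # two-point frontal-plane moment-balance decomposition, by category
    acc_med <- numeric(3L); acc_lat <- numeric(3L); acc_tot <- numeric(3L)
    add_cat <- function(P, Fm, Cm) {
      a <- -(Fm %*% axial)[, 1L]
      rx <- P[, 1L] - lat_cp[1L]; ry <- P[, 2L] - lat_cp[2L]
      rz <- P[, 3L] - lat_cp[3L]
      mx <- ry * Fm[, 3L] - rz * Fm[, 2L] + Cm[, 1L]
      my <- rz * Fm[, 1L] - rx * Fm[, 3L] + Cm[, 2L]
      mz <- rx * Fm[, 2L] - ry * Fm[, 1L] + Cm[, 3L]
      m_ap <- mx * ap[1L] + my * ap[2L] + mz * ap[3L]
      c_med <- m_ap / w
      c(sum(c_med), sum(a - c_med), sum(a))
    }
    v <- add_cat(matrix(0, 1L, 3L), matrix(ext_f, 1L, 3L),
                 matrix(ext_m, 1L, 3L))
    acc_med[1L] <- v[1L]; acc_lat[1L] <- v[2L]; acc_tot[1L] <- v[3L]
    if (!is.null(ligaments)) {
      v <- add_cat(fem, lf, matrix(0, nrow(lf), 3L))
      acc_med[3L] <- v[1L]; acc_lat[3L] <- v[2L]; acc_tot[3L] <- v[3L]
    }

    if (!is.null(mus)) {
      prox <- mus_prox0 %*% t(R)
      d_m <- mus_dist - prox
      len_m <- sqrt(rowSums(d_m * d_m))
      u <- d_m / len_m
      r_sag <- prox[, 1L] * u[, 2L] - prox[, 2L] * u[, 1L]
      f_min <- numeric(length(mus_fmax))
      if (length(gas_idx)) {
        d_a <- cop - ankle
        m_ank <- d_a[1L] * f_grf[2L] - d_a[2L] * f_grf[1L]
        f_gas <- gastroc_share * max(0, m_ank) / ankle_arm
        f_min[gas_idx] <- pmin(f_gas * gas_split, mus_fmax[gas_idx])
      }
      m_req <- -(ext_m[3L] + lig_mz)
      sol <- recruit_sagittal_core(m_req, r_sag, mus_fmax, f_min,
                                   recruitment_exponent)
      forces <- sol$forces

      # unilateral contact: the condyles can only push. If the passive +
      # sagittal-recruited solution would put a compartment in tension,
      # re-recruit with a second constraint holding that compartment at a
      # marginal compressive load (1% body weight), mirroring contact
      # elements that cannot pull.
      a_unit <- -(u %*% axial)[, 1L]
      rx <- prox[, 1L] - lat_cp[1L]; ry <- prox[, 2L] - lat_cp[2L]
      rz <- prox[, 3L] - lat_cp[3L]
      m_unit <- (ry * u[, 3L] - rz * u[, 2L]) * ap[1L] +
        (rz * u[, 1L] - rx * u[, 3L]) * ap[2L] +
        (rx * u[, 2L] - ry * u[, 1L]) * ap[3L]
      c_med_unit <- m_unit / w
      c_lat_unit <- a_unit - c_med_unit
      floor_load <- 0.01 * anthro$body_mass * gravity
      lat_pass <- acc_lat[1L] + acc_lat[3L]
      med_pass <- acc_med[1L] + acc_med[3L]
      lat_tot <- lat_pass + sum(c_lat_unit * forces)
      med_tot <- med_pass + sum(c_med_unit * forces)
      if (lat_tot < floor_load || med_tot < floor_load) {
        guard <- if (lat_tot < floor_load) {
          list(unit = c_lat_unit, target = floor_load - lat_pass)
        } else {
          list(unit = c_med_unit, target = floor_load - med_pass)
        }
        mg_guard <- data.frame(name = mus$name, f_max = mus_fmax,
                               r_sag = r_sag, r_front = guard$unit,
                               stringsAsFactors = FALSE)
        rec2 <- recruit_muscles(m_req, m_front = guard$target,
                                muscles = mg_guard,
                                exponent = recruitment_exponent,
                                f_min = f_min)
        forces <- unname(rec2$forces)
      }
      resid_max <- max(resid_max, abs(m_req - sum(r_sag * forces)))
      mf[i, ] <- forces
      v <- add_cat(prox, u * forces, matrix(0, nrow(u), 3L))
      acc_med[2L] <- v[1L]; acc_lat[2L] <- v[2L]; acc_tot[2L] <- v[3L]
    }
    out[i, 1:3] <- acc_med
    out[i, 4:6] <- acc_lat
    out[i, 7:9] <- acc_tot
    out[i, 10L] <- sum(acc_med); out[i, 11L] <- sum(acc_lat)
    out[i, 12L] <- sum(acc_tot)
  }

  series <- structure(list(time = kin$time_s,
                           by_category = as.data.frame(out)),
                      class = "decomposition_series")
  structure(list(series = series, ekam = ekam, muscle_forces = mf,
                 residual = resid_max,
                 subject_id = trial$subject_id, group = trial$group,
                 limb = trial$limb, trial = trial$trial,
                 events = trial$events,
                 body_weight = anthro$body_mass * gravity),
            class = "trial_result")
}

#' Aggregate per-trial phase summaries to subject level
#'
#' Averages each subject's percent contributions over trials and limbs
#' before any group statistics (the subject is the experimental unit,
#' avoiding pseudo-replication).
#'
#' @param trial_rows Long data frame of per-trial rows: `subject_id`,
#'   `limb`, `trial`, `phase`, `compartment`, `category`, `percent`.
#' @return Long data frame: one row per subject x phase x compartment x
#'   category with the subject-mean `percent`.
#' @export
subject_summaries <- function(trial_rows) {
  agg <- aggregate(percent ~ subject_id + phase + compartment + category,
                   data = trial_rows, FUN = mean)
  agg[order(agg$subject_id, agg$phase, agg$compartment, agg$category), ,
      drop = FALSE]
}

#' Pipeline configuration
#'
#' Bundles the cohort templates, model parameter sets and analysis options
#' for [run_pipeline()]. Group seeds are derived deterministically from the
#' master seed.
#'
#' @param seed Master seed (integer).
#' @param healthy,koa [cohort_template()]s; defaults are the two presets
#'   with seeds `2 * seed` and `2 * seed + 1`.
#' @param ligaments Calibrated [ligament_set()] or `NULL` (disable).
#' @param muscles `"muscle_set"` or `NULL` (disable).
#' @param recruitment_exponent Recruitment criterion order (default 3).
#' @param phase_mode `"events"` (default; sub-phases from the trial's gait
#'   events) or `"fractions"` (fixed 16%/84% stance fractions).
#' @param contribution_mode `"integral"` or `"mean_ratio"` (see
#'   [phase_percent_contributions()]).
#' @param alpha Significance level in (0, 1), default 0.05.
#' @param out_dir Optional output directory for [render_reports()].
#' @return Object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(seed = 0L,
                            healthy = cohort_template("healthy",
                                                      seed = 2L * seed),
                            koa = cohort_template("koa",
                                                  seed = 2L * seed + 1L),
                            ligaments = default_ligament_params(),
                            muscles = default_muscle_set(),
                            recruitment_exponent = 3,
                            phase_mode = c("events", "fractions"),
                            contribution_mode = c("integral", "mean_ratio"),
                            alpha = 0.05,
                            out_dir = NULL) {
  if (alpha <= 0 || alpha >= 1) {
    stop("invalid config: alpha must lie in (0, 1)", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), healthy = healthy, koa = koa,
                 ligaments = ligaments, muscles = muscles,
                 recruitment_exponent = recruitment_exponent,
                 phase_mode = match.arg(phase_mode),
                 contribution_mode = match.arg(contribution_mode),
                 alpha = alpha, out_dir = out_dir),
            class = "pipeline_config")
}

config_digest <- function(config) {
  tmp <- tempfile(fileext = ".rds")
  on.exit(unlink(tmp))
  cfg <- unclass(config)
  cfg$out_dir <- NULL  # the digest describes the computation, not the sink
  # version 2 serialization is stable across the R versions we support
  saveRDS(cfg, tmp, version = 2)
  unname(tools::md5sum(tmp))
}

trial_phase_rows <- function(tr, config) {
  events <- tr$events
  if (config$phase_mode == "fractions") {
    t0 <- min(tr$series$time); t1 <- max(tr$series$time)
    events <- c(hs_ipsi = t0, to_contra = t0 + 0.16 * (t1 - t0),
                hs_contra = t0 + 0.84 * (t1 - t0), to_ipsi = t1)
  }
  ph <- phase_percent_contributions(tr$series, events,
                                    mode = config$contribution_mode)
  long <- do.call(rbind, lapply(c("external", "muscle", "ligament"),
    function(cat) data.frame(subject_id = tr$subject_id, limb = tr$limb,
                             trial = tr$trial, phase = ph$phase,
                             compartment = ph$compartment, category = cat,
                             percent = ph[[cat]],
                             stringsAsFactors = FALSE)))
  long
}

# 101-point %BW contribution curves for one trial (per compartment and
# category, plus compartment totals).
trial_curves <- function(tr) {
  bc <- tr$series$by_category
  tn <- time_normalize(tr$series$time, bc, n_points = 101L)
  vals <- tn$values / tr$body_weight * 100
  data.frame(percent_stance = rep(tn$percent, ncol(vals)),
             channel = rep(colnames(vals), each = 101L),
             value_pct_bw = as.numeric(vals), stringsAsFactors = FALSE)
}

run_group <- function(template, config, label) {
  cohort <- generate_cohort(template)
  rows <- vector("list", length(cohort$trials))
  curves <- vector("list", length(cohort$trials))
  ekam_peak <- numeric(length(cohort$trials))
  resid <- numeric(length(cohort$trials))
  for (j in seq_along(cohort$trials)) {
    trial <- cohort$trials[[j]]
    tr <- tryCatch(
      run_trial(trial, ligaments = config$ligaments,
                muscles = config$muscles,
                recruitment_exponent = config$recruitment_exponent),
      error = function(e) stop("pipeline stage `decompose` failed for ",
                               label, " trial ", trial$subject_id, "/",
                               trial$limb, "/", trial$trial, ": ",
                               conditionMessage(e), call. = FALSE))
    rows[[j]] <- tryCatch(
      trial_phase_rows(tr, config),
      error = function(e) stop("pipeline stage `summarize` failed for ",
                               label, " trial ", trial$subject_id, "/",
                               trial$limb, "/", trial$trial, ": ",
                               conditionMessage(e), call. = FALSE))
    cur <- trial_curves(tr)
    cur$subject_id <- tr$subject_id
    curves[[j]] <- cur
    ekam_peak[j] <- max(tr$ekam)
    resid[j] <- tr$residual
  }
  trial_rows <- do.call(rbind, rows)
  trial_rows$group <- label
  subj <- subject_summaries(trial_rows)
  subj$group <- label
  all_curves <- do.call(rbind, curves)
  subj_curves <- aggregate(value_pct_bw ~ subject_id + channel +
                             percent_stance, data = all_curves, FUN = mean)
  curve_stats <- aggregate(value_pct_bw ~ channel + percent_stance,
                           data = subj_curves,
                           FUN = function(v) c(mean = mean(v),
                                               sd = sd0(v)))
  curve_stats <- data.frame(group = label,
                            channel = curve_stats$channel,
                            percent_stance = curve_stats$percent_stance,
                            mean_pct_bw = curve_stats$value_pct_bw[, "mean"],
                            sd_pct_bw = curve_stats$value_pct_bw[, "sd"],
                            stringsAsFactors = FALSE)
  ekam_subj <- data.frame(subject_id = vapply(cohort$trials,
                                              function(t) t$subject_id, ""),
                          peak_ekam = ekam_peak)
  ekam_subj <- aggregate(peak_ekam ~ subject_id, ekam_subj, mean)
  list(trial_rows = trial_rows, subjects = cohort$subjects,
       subject_rows = subj, curves = curve_stats,
       peak_ekam = ekam_subj, max_residual = max(resid))
}

sd0 <- function(v) if (length(v) < 2L) 0 else sd(v)

#' Run the full decomposition pipeline on two synthetic cohorts
#'
#' Simulate (healthy and KOA cohorts) -> ligament forces -> intersegmental
#' loads -> muscle recruitment -> source assembly -> two-point
#' decomposition -> stance sub-phase percent summaries -> group statistics.
#' Deterministic for a fixed config (including seed). When
#' `config$out_dir` is set the report files and a run manifest are written
#' via [render_reports()].
#'
#' @param config A [pipeline_config()].
#' @return Object of class `"pipeline_result"`: subject tables, per-trial
#'   and per-subject percent summaries, between-group statistics
#'   (`$stats`), within-group category contrasts, group mean +/- SD curve
#'   tables, per-group peak EKAM, and the run manifest.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "pipeline_config")) {
    stop("invalid config: use pipeline_config()", call. = FALSE)
  }
  healthy <- run_group(config$healthy, config, "healthy")
  koa <- run_group(config$koa, config, "koa")
  stats <- compare_groups(healthy$subject_rows, koa$subject_rows,
                          alpha = config$alpha, family = "compartment",
                          labels = c("healthy", "koa"))
  within <- rbind(
    cbind(group = "healthy",
          category_contrasts(healthy$subject_rows, config$alpha)),
    cbind(group = "koa", category_contrasts(koa$subject_rows,
                                            config$alpha)))
  manifest <- list(package = "kneeload",
                   version = as.character(packageVersion("kneeload")),
                   seed = config$seed,
                   group_seeds = c(healthy = config$healthy$seed,
                                   koa = config$koa$seed),
                   config_md5 = config_digest(config),
                   n_trials = c(healthy = nrow(healthy$trial_rows) / 36L,
                                koa = nrow(koa$trial_rows) / 36L),
                   max_recruitment_residual_Nm =
                     max(healthy$max_residual, koa$max_residual))
  res <- structure(list(config = config,
                        subjects = rbind(healthy$subjects, koa$subjects),
                        trial_rows = rbind(healthy$trial_rows,
                                           koa$trial_rows),
                        subject_rows = rbind(healthy$subject_rows,
                                             koa$subject_rows),
                        stats = stats, within_group = within,
                        curves = rbind(healthy$curves, koa$curves),
                        peak_ekam = list(healthy = healthy$peak_ekam,
                                         koa = koa$peak_ekam),
                        manifest = manifest),
                   class = "pipeline_result")
  if (!is.null(config$out_dir)) render_reports(res, config$out_dir)
  res
}

group_phase_table <- function(subject_rows, compartment) {
  sub <- subject_rows[subject_rows$compartment == compartment, ]
  agg <- aggregate(percent ~ group + phase + category, data = sub,
                   FUN = function(v) c(mean = mean(v), sd = sd0(v)))
  data.frame(group = agg$group, phase = agg$phase, category = agg$category,
             mean_pct = agg$percent[, "mean"], sd_pct = agg$percent[, "sd"],
             stringsAsFactors = FALSE)
}

#' Write report tables and curve files
#'
#' One summary table per compartment (rows = stance phase x force
#' category, group mean +/- SD and the adjusted between-group p value) and
#' one 101-point mean +/- SD curve file per compartment, plus the full
#' statistics tables, subject summaries and the run manifest. Output is
#' deterministic for a fixed pipeline result.
#'
#' @param results A `"pipeline_result"`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
render_reports <- function(results, out_dir) {
  if (!inherits(results, "pipeline_result") || !nrow(results$subject_rows)) {
    stop("empty input: no pipeline results to report", call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (cn in c("total", "medial", "lateral")) {
    tab <- group_phase_table(results$subject_rows, cn)
    st <- results$stats[results$stats$compartment == cn,
                        c("phase", "category", "p_adj")]
    tab <- merge(tab, st, by = c("phase", "category"), sort = FALSE)
    tab <- tab[order(match(tab$phase, stance_phases),
                     match(tab$category,
                           c("external", "muscle", "ligament")),
                     tab$group), c("phase", "category", "group",
                                   "mean_pct", "sd_pct", "p_adj")]
    write_csv_full(tab, file.path(out_dir,
                                  paste0("table_", cn, ".csv")))
    cur <- results$curves[grepl(paste0("_", substr(cn, 1L, 3L), "$"),
                                results$curves$channel) |
                            results$curves$channel ==
                              paste0("f_", substr(cn, 1L, 3L)) |
                            (cn == "total" &
                               results$curves$channel == "f_total"), ]
    cur <- cur[order(cur$group, cur$channel, cur$percent_stance), ]
    write_csv_full(cur, file.path(out_dir, paste0("curves_", cn, ".csv")))
  }
  write_csv_full(results$stats, file.path(out_dir, "group_stats.csv"))
  write_csv_full(results$within_group,
                 file.path(out_dir, "within_group_contrasts.csv"))
  write_csv_full(results$subject_rows,
                 file.path(out_dir, "subject_summaries.csv"))
  jsonlite::write_json(results$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
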