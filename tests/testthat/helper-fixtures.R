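# Shared fixtures. Everything is generated in code; the only state is a
# per-session cache so the full default-cohort pipeline run (the heaviest
# fixture) is computed once and shared by the tests that need it.

.kneeload_cache <- new.env(parent = emptyenv())

# Full pipeline at the default study conditions (20 + 20 subjects, 2 limbs,
# 10 trials per limb, master seed 0).
get_full_run <- function() {
  if (is.null(.kneeload_cache$full_run)) {
    .kneeload_cache$full_run <- run_pipeline(pipeline_config(seed = 0L))
  }
  .kneeload_cache$full_run
}

make_test_subject <- function(group = "healthy", varus = 0.5,
                              speed = 1.2, quad = 1, gas = 1,
                              ekam = 1, noise = TRUE) {
  ns <- if (noise) list(angle_deg = 0.5, grf_frac = 0.02, cop_m = 0.002)
        else list(angle_deg = 0, grf_frac = 0, cop_m = 0)
  gait_subject(paste0("t_", group), body_mass = 65.7, height = 1.58,
               speed = speed, varus_deg = varus, ekam_scale = ekam,
               strength_scale_quad = quad, strength_scale_gastroc = gas,
               noise_sd = ns, group = group)
}

# A deterministic bag of random force sources for oracle tests.
random_sources <- function(n, rng_unit = 1000) {
  ids <- sprintf("s%02d", seq_len(n))
  cats <- sample(c("external", "muscle", "ligament"), n, replace = TRUE)
  do.call(rbind, lapply(seq_len(n), function(i) {
    couple <- if (cats[i] == "external") runif(3, -50, 50) else c(0, 0, 0)
    force_source(ids[i], cats[i],
                 point = runif(3, -0.1, 0.1),
                 force = runif(3, -rng_unit, rng_unit),
                 couple = couple)
  }))
}

# Independent monolithic oracle: solve the two-unknown quasi-static system
# (axial force balance + frontal moment balance about the lateral contact
# point) for the compartment loads, without using the per-source formula.
oracle_compartment_loads <- function(sources, geom) {
  a_tot <- sum(axial_component(sources, geom))
  m_tot <- sum(frontal_moment_about(sources, geom$lateral_cp, geom))
  # unknowns x = (F_med, F_lat):  x1 + x2 = a_tot ;  w * x1 = m_tot
  A <- rbind(c(1, 1), c(geom$width, 0))
  x <- solve(A, c(a_tot, m_tot))
  c(f_med = x[1L], f_lat = x[2L])
}

# Brute-force Benjamini-Hochberg step-up reference, written directly from
# the step-up definition (sorted p * m / rank, cumulative minimum from the
# largest rank down, capped at 1).
bh_reference <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- (m / seq_len(m)) * p[o]
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}
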