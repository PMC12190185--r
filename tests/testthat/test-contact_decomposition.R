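geom_default <- contact_geometry(width = 0.05)

test_that("axial component is the compressive projection", {
  g <- geom_default
  expect_equal(axial_component(
    force_source("a", "external", c(0, 0, 0), c(0, -500, 0)), g), 500)
  expect_equal(axial_component(
    force_source("a", "external", c(0, 0, 0), c(120, 0, 0)), g), 0)
  expect_equal(axial_component(
    force_source("a", "external", c(0, 0, 0), c(0, -400, 300)), g), 400)
})

test_that("frontal moment is adduction-positive about the AP axis", {
  g <- geom_default
  pt <- c(0, 0, 0)
  # line of action through the reference point: zero lever
  s <- force_source("a", "muscle", point = c(0, 0.05, 0),
                    force = c(0, -300, 0))
  expect_equal(frontal_moment_about(s, c(0, 0.2, 0), g), 0)
  # vertical 700 N load 0.04 m medial of the point -> 28 N m, loading medial
  s <- force_source("a", "external", point = c(0, 0, 0.04),
                    force = c(0, -700, 0))
  expect_equal(frontal_moment_about(s, pt, g), 28)
  # couple passthrough
  s <- force_source("a", "external", point = pt, force = c(0, -100, 0),
                    couple = c(5, 0, 0))
  expect_equal(frontal_moment_about(s, pt, g), 5)
})

test_that("per-source decomposition solves the two-point moment balance", {
  g <- contact_geometry(width = 0.05)
  # one source with axial 500 N and M(lateral_cp) = 15 N m:
  # vertical -500 N applied 0.03 m medial of the lateral contact point
  s <- force_source("a", "external", point = c(0, 0, g$lateral_cp[3L] + 0.03),
                    force = c(0, -500, 0))
  d <- decompose_frame(s, g)
  expect_equal(d$per_source$c_med, 300)
  expect_equal(d$per_source$c_lat, 200)
  expect_equal(d$per_source$c_tot, 500)
  expect_equal(unname(oracle_compartment_loads(s, g)),
               c(d$f_med, d$f_lat), tolerance = 1e-12)
  # zero frontal moment about the lateral point -> all load lateral
  s0 <- force_source("a", "external", point = g$lateral_cp,
                     force = c(0, -500, 0))
  d0 <- decompose_frame(s0, g)
  expect_equal(d0$f_med, 0)
  expect_equal(d0$f_lat, 500)
  # linearity: a 50/50 split halves per-source values, totals unchanged
  s_half <- rbind(s, s)
  s_half$source_id <- c("a1", "a2")
  s_half[, c("fx", "fy", "fz")] <- s_half[, c("fx", "fy", "fz")] / 2
  dh <- decompose_frame(s_half, g)
  expect_equal(dh$per_source$c_med, c(150, 150))
  expect_equal(dh$f_med, d$f_med)
  expect_equal(dh$f_lat, d$f_lat)
})

test_that("decomposition matches the monolithic equilibrium oracle", {
  withr::with_seed(101, {
    for (rep in 1:200) {
      g <- contact_geometry(width = runif(1, 0.03, 0.08))
      src <- random_sources(sample(3:10, 1))
      d <- decompose_frame(src, g)
      o <- oracle_compartment_loads(src, g)
      scale <- max(1, abs(o))
      expect_lt(abs(d$f_med - o[["f_med"]]) / scale, 1e-9)
      expect_lt(abs(d$f_lat - o[["f_lat"]]) / scale, 1e-9)
      expect_lt(abs(d$f_med + d$f_lat - d$f_total) /
                  max(1, abs(d$f_total)), 1e-9)
      # per-source sums reproduce the totals
      expect_equal(sum(d$per_source$c_med), d$f_med)
      expect_equal(sum(d$per_source$c_lat), d$f_lat)
    }
  })
})

test_that("decomposition is additive over source sets", {
  withr::with_seed(7, {
    g <- contact_geometry()
    a <- random_sources(4)
    b <- random_sources(5)
    b$source_id <- paste0("b_", b$source_id)
    da <- decompose_frame(a, g)
    db <- decompose_frame(b, g)
    dab <- decompose_frame(rbind(a, b), g)
    expect_equal(dab$f_med, da$f_med + db$f_med, tolerance = 1e-12)
    expect_equal(dab$f_lat, da$f_lat + db$f_lat, tolerance = 1e-12)
    expect_equal(dab$f_total, da$f_total + db$f_total, tolerance = 1e-12)
  })
})

test_that("moments about the medial point give the same lateral load", {
  withr::with_seed(13, {
    g <- contact_geometry(width = 0.046)
    src <- random_sources(6)
    a <- sum(axial_component(src, g))
    m_lat <- sum(frontal_moment_about(src, g$lateral_cp, g))
    m_med <- sum(frontal_moment_about(src, g$medial_cp, g))
    # algebraic identity: M_med = M_lat - A * w
    expect_equal(m_med, m_lat - a * g$width, tolerance = 1e-9)
    f_lat_via_med <- -m_med / g$width
    d <- decompose_frame(src, g)
    expect_equal(f_lat_via_med, d$f_lat, tolerance = 1e-9)
  })
})

test_that("moving a vertical load medially shifts load to the medial side", {
  g <- contact_geometry()
  z <- seq(-0.03, 0.03, by = 0.01)
  cm <- cl <- numeric(length(z))
  for (i in seq_along(z)) {
    d <- decompose_frame(force_source("a", "external", c(0, 0, z[i]),
                                      c(0, -600, 0)), g)
    cm[i] <- d$f_med; cl[i] <- d$f_lat
  }
  expect_true(all(diff(cm) > 0))
  expect_true(all(diff(cl) < 0))
})

test_that("trial decomposition carries time and preserves invariants", {
  g <- contact_geometry()
  expect_error(decompose_trial(list(), g), "empty input")
  s <- force_source("a", "external", c(0, 0, 0.01), c(0, -500, 0))
  one <- decompose_trial(list(s), g, time = 0)
  expect_identical(length(one$time), 1L)
  ten <- decompose_trial(rep(list(s), 10L), g, time = 0:9 / 100)
  expect_true(all(apply(ten$by_category, 2L, function(x) all(x == x[1L]))))
  withr::with_seed(19, {
    frames <- lapply(1:50, function(i) random_sources(5))
    ser <- decompose_trial(frames, g, time = (1:50) / 100)
    for (i in 1:50) {
      o <- oracle_compartment_loads(frames[[i]], g)
      expect_lt(abs(ser$by_category$f_med[i] - o[["f_med"]]) /
                  max(1, abs(o[["f_med"]])), 1e-9)
    }
    expect_equal(ser$by_category$f_med + ser$by_category$f_lat,
                 ser$by_category$f_total, tolerance = 1e-12)
  })
  expect_error(decompose_trial(rep(list(s), 3L), g, time = c(0, 0, 1)),
               "time-ordered")
})

test_that("degenerate contact geometry is rejected", {
  expect_error(contact_geometry(width = 0), "degenerate|invalid")
  expect_error(contact_geometry(medial_cp = c(0, 0, 0),
                                lateral_cp = c(0, 0, 0)),
               "degenerate")
})

test_that("decomposition CSV round trip is bit-exact", {
  withr::with_seed(23, {
    g <- contact_geometry()
    frames <- lapply(1:7, function(i) random_sources(4))
    ser <- decompose_trial(frames, g, time = (0:6) / 100)
    path <- withr::local_tempfile(fileext = ".csv")
    write_decomposition(ser, path)
    back <- read_decomposition(path)
    expect_identical(back$time, ser$time)
    for (cl in names(ser$by_category)) {
      expect_identical(back$by_category[[cl]], ser$by_category[[cl]])
    }
  })
})
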