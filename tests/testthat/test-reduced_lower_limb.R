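tiny_anthro <- function() {
  # near-massless segments isolate the GRF terms
  anthropometry(65, 1.6, shank_mass_frac = 1e-9, foot_mass_frac = 1e-9)
}

test_that("intersegmental loads reduce to the GRF lever geometry", {
  an <- tiny_anthro()
  kjc <- c(0, 0.45, 0)
  # GRF line through the knee centre: no moment, ekam = 0
  pf <- pose_frame(0.1, 10, 1, 0, kjc)
  gf <- grf_frame(0.1, c(0, 700, 0), cop = c(0, 0, 0))
  il <- intersegmental_loads(pf, gf, an)
  expect_equal(il$ekam, 0, tolerance = 1e-6)
  expect_equal(il$moment, c(0, 0, 0), tolerance = 1e-6)
  expect_equal(il$force, c(0, -700, 0), tolerance = 1e-5)
  # 0.04 m frontal lever arm -> |ekam| = 28 N m, medial-loading for a
  # medially passing vertical GRF
  gf2 <- grf_frame(0.1, c(0, 700, 0), cop = c(0, 0, 0.04))
  il2 <- intersegmental_loads(pf, gf2, an)
  expect_equal(abs(il2$ekam), 28, tolerance = 1e-6)
  expect_gt(il2$ekam, 0)
  # gravity-only: net force equals total segment weight
  an3 <- anthropometry(80, 1.7)
  gf3 <- grf_frame(0.1, c(0, 0, 0), cop = c(0, 0, 0))
  il3 <- intersegmental_loads(pf, gf3, an3)
  w_tot <- (an3$shank_mass + an3$foot_mass) * 9.81
  expect_equal(il3$force[2L], w_tot, tolerance = 1e-9)
  expect_error(intersegmental_loads(pf, grf_frame(0.2, c(0, 1, 0),
                                                  c(0, 0, 0)), an),
               "alignment error")
})

test_that("moment transfer obeys M' = M + d x F under a reference shift", {
  # near-massless segments: segment centres of mass are derived from the
  # knee centre, so only the GRF term must obey the transfer identity
  an <- tiny_anthro()
  gf <- grf_frame(0, c(30, 650, -12), cop = c(0.08, 0, 0.03),
                  free_moment = 4)
  d <- c(0.02, -0.05, 0.01)
  pf1 <- pose_frame(0, 12, 3, 1, c(0, 0.44, 0))
  pf2 <- pose_frame(0, 12, 3, 1, c(0, 0.44, 0) + d)
  il1 <- intersegmental_loads(pf1, gf, an)
  il2 <- intersegmental_loads(pf2, gf, an)
  # shifting the knee centre by d adds d x (external resultant) = -d x F_net
  expect_equal(il2$moment, il1$moment + cross3(d, -il1$force),
               tolerance = 1e-6)
  expect_equal(il2$force, il1$force, tolerance = 1e-12)
})

test_that("quasi-statics is linear: doubling the GRF doubles the loads", {
  an <- tiny_anthro()
  pf <- pose_frame(0, 15, 2, 0, c(0.02, 0.43, 0))
  gf1 <- grf_frame(0, c(40, 600, -10), cop = c(0.06, 0, 0.03))
  gf2 <- grf_frame(0, 2 * c(40, 600, -10), cop = c(0.06, 0, 0.03))
  il1 <- intersegmental_loads(pf, gf1, an)
  il2 <- intersegmental_loads(pf, gf2, an)
  expect_equal(il2$ekam, 2 * il1$ekam, tolerance = 1e-6)
  expect_equal(il2$force, 2 * il1$force, tolerance = 1e-4)
})

test_that("recruitment solves the textbook single- and two-muscle cases", {
  one <- data.frame(name = "m", f_max = 2000, r_sag = 0.04, r_front = 0)
  rec <- recruit_muscles(20, muscles = one)
  expect_equal(unname(rec$forces), 500, tolerance = 1e-9)
  expect_equal(unname(rec$residual[["sag"]]), 0, tolerance = 1e-9)
  # identical muscles share the load equally
  two <- data.frame(name = c("a", "b"), f_max = c(1500, 1500),
                    r_sag = c(0.03, 0.03), r_front = c(0, 0))
  rec2 <- recruit_muscles(18, muscles = two)
  expect_equal(unname(rec2$forces[1L]), unname(rec2$forces[2L]),
               tolerance = 1e-9)
  # cubic criterion: same arm, different strengths -> F1/F2 = (M1/M2)^(3/2)
  mix <- data.frame(name = c("a", "b"), f_max = c(1000, 600),
                    r_sag = c(0.04, 0.04), r_front = c(0, 0))
  rec3 <- recruit_muscles(20, muscles = mix)
  expect_equal(unname(rec3$forces[1L] / rec3$forces[2L]), (1000 / 600)^1.5,
               tolerance = 1e-9)
  expect_error(recruit_muscles(10, muscles = mix[0, ]), "infeasibility")
})

test_that("recruitment matches the closed form over a seeded grid", {
  withr::with_seed(31, {
    for (rep in 1:100) {
      fm <- runif(2, 200, 4000)
      r <- runif(1, 0.01, 0.08)
      m <- runif(1, 0.5, 0.9) * r * sum(fm)  # inside capacity
      mg <- data.frame(name = c("a", "b"), f_max = fm,
                       r_sag = c(r, r), r_front = c(0, 0))
      rec <- recruit_muscles(m, muscles = mg)
      ratio <- (fm[1L] / fm[2L])^1.5
      if (all(rec$forces < fm - 1e-6)) {
        expect_lt(abs(rec$forces[[1L]] / rec$forces[[2L]] - ratio) / ratio,
                  1e-6)
      }
      expect_lt(abs(rec$residual[["sag"]]), 1e-6)
    }
  })
})

test_that("unreachable demand saturates and reports the residual", {
  mg <- data.frame(name = c("a", "b"), f_max = c(100, 50),
                   r_sag = c(0.02, 0.03), r_front = c(0, 0))
  rec <- recruit_muscles(50, muscles = mg)  # capacity 0.02*100+0.03*50=3.5
  expect_equal(unname(rec$forces), c(100, 50), tolerance = 1e-6)
  expect_equal(unname(rec$residual[["sag"]]), 50 - 3.5, tolerance = 1e-6)
  # feasibility: residual is zero whenever capacity covers the demand
  withr::with_seed(37, {
    for (rep in 1:50) {
      fm <- runif(3, 100, 3000)
      r <- runif(3, 0.01, 0.06)
      m <- runif(1) * 0.95 * sum(r * fm)
      mg <- data.frame(name = c("a", "b", "c"), f_max = fm, r_sag = r,
                       r_front = 0)
      rec <- recruit_muscles(m, muscles = mg)
      expect_lt(abs(rec$residual[["sag"]]), 1e-6)
    }
  })
})

test_that("lower force bounds act as prescribed baselines", {
  mg <- data.frame(name = c("quad", "gas"), f_max = c(3000, 1200),
                   r_sag = c(-0.045, 0.03), r_front = c(0, 0))
  # gastrocnemius pinned at 400 N by ankle demand; quadriceps must cancel
  # its knee flexion moment plus the 10 N m extensor demand
  rec <- recruit_muscles(-10, muscles = mg, f_min = c(0, 400))
  expect_equal(unname(rec$forces[["gas"]]), 400, tolerance = 1e-8)
  expect_equal(unname(rec$forces[["quad"]]), (10 + 0.03 * 400) / 0.045,
               tolerance = 1e-6)
})

test_that("two-constraint recruitment satisfies both moment balances", {
  # 2 muscles, 2 constraints: unique solution from the linear system
  mg <- data.frame(name = c("a", "b"), f_max = c(2500, 2500),
                   r_sag = c(0.04, 0.035), r_front = c(0.02, -0.025))
  A <- rbind(mg$r_sag, mg$r_front)
  target <- c(30, -5)
  expected <- solve(A, target)
  expect_true(all(expected > 0))
  rec <- recruit_muscles(target[1L], m_front = target[2L], muscles = mg)
  expect_equal(unname(rec$forces), expected, tolerance = 1e-4)
  expect_lt(max(abs(rec$residual)), 1e-4)
  # 3 muscles: constraints hold and the cost is no worse than feasible
  # alternatives constructed by perturbing along the one-dimensional
  # null space of the constraint matrix
  mg3 <- data.frame(name = c("a", "b", "c"), f_max = c(3000, 1500, 1000),
                    r_sag = c(0.045, 0.03, 0.035),
                    r_front = c(0.01, -0.02, 0.015))
  rec3 <- recruit_muscles(40, m_front = 3, muscles = mg3)
  expect_lt(max(abs(rec3$residual)), 1e-4)
  cost <- function(f) sum((f / mg3$f_max)^3)
  ns <- MASS::Null(t(rbind(mg3$r_sag, mg3$r_front)))[, 1L]
  for (step in c(-40, -10, 10, 40)) {
    alt <- rec3$forces + step * ns
    if (all(alt >= 0 & alt <= mg3$f_max)) {
      expect_lte(cost(rec3$forces), cost(alt) + 1e-9)
    }
  }
})

test_that("muscle geometry produces physiologic signed moment arms", {
  mg <- muscle_geometry(knee_pose(10, 1, 0))
  expect_true(all(abs(mg$r_sag) < 0.1))
  expect_true(all(abs(mg$r_front) < 0.1))
  # knee extensors act opposite in sign to the flexors
  quad <- mg$r_sag[mg$name %in% c("vasti", "rectus_femoris")]
  flex <- mg$r_sag[mg$name %in% c("gastroc_med", "gastroc_lat",
                                  "hamstrings_med", "hamstrings_lat")]
  expect_true(all(sign(quad) == sign(quad[1L])))
  expect_true(all(sign(flex) == -sign(quad[1L])))
  # medial muscles load medially, lateral muscles laterally
  expect_gt(mg$r_front[mg$name == "gastroc_med"], 0)
  expect_lt(mg$r_front[mg$name == "gastroc_lat"], 0)
})

test_that("assembled sources are categorized and complete", {
  pose <- knee_pose(10, 1, 0)
  an <- anthropometry(65, 1.6)
  pf <- pose_frame(0, 10, 1, 0, c(0, 0.43, 0))
  gf <- grf_frame(0, c(20, 640, -8), cop = c(0.03, 0, 0.03))
  il <- intersegmental_loads(pf, gf, an)
  ligs <- ligament_sources(pose)
  mg <- muscle_geometry(pose)
  rec <- recruit_muscles(-25, muscles = mg)
  src <- assemble_sources(pose, il, rec, mg, ligs)
  n_active <- sum(rec$forces > 1e-9)
  expect_identical(nrow(src), 1L + n_active + 22L)
  expect_identical(sum(src$category == "external"), 1L)
  # external alone -> the decomposition attributes everything to external
  only_ext <- assemble_sources(pose, il, NULL, NULL, NULL)
  expect_identical(nrow(only_ext), 1L)
  d <- decompose_frame(only_ext, contact_geometry())
  expect_equal(d$by_category$c_tot[d$by_category$category == "external"],
               d$f_total)
  # a symmetric muscle pair loads both compartments equally
  sym <- data.frame(name = c("med", "lat"), f_max = c(1000, 1000),
                    px = c(-0.03, -0.03), py = c(0.01, 0.01),
                    pz = c(0.025, -0.025),
                    dx = c(-0.04, -0.04), dy = c(-0.38, -0.38),
                    dz = c(0.025, -0.025))
  mg_sym <- muscle_geometry(knee_pose(), sym)
  fr <- data.frame(source_id = mg_sym$name, category = "muscle",
                   px = mg_sym$px, py = mg_sym$py, pz = mg_sym$pz,
                   fx = 500 * mg_sym$ux, fy = 500 * mg_sym$uy,
                   fz = 500 * mg_sym$uz, cx = 0, cy = 0, cz = 0,
                   stringsAsFactors = FALSE)
  ds <- decompose_frame(fr, contact_geometry())
  expect_equal(ds$f_med, ds$f_lat, tolerance = 1e-9)
})
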