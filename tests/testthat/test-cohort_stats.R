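test_that("time normalization is exact on lines and tight on smooth curves", {
  tn <- time_normalize(c(0, 0.5, 1), c(3, 3, 3))
  expect_identical(length(tn$values), 101L)
  expect_true(all(tn$values == 3))
  # linear ramp: grid values k/100, endpoints exact
  t <- seq(0, 1, by = 0.01)
  tn2 <- time_normalize(t, t)
  expect_equal(tn2$values, seq(0, 1, length.out = 101L), tolerance = 1e-12)
  expect_identical(tn2$values[1L], 0)
  expect_identical(tn2$values[101L], 1)
  # sine sampled at 100 Hz: linear interpolation error < 1e-3
  t3 <- seq(0, 1, by = 0.01)
  tn3 <- time_normalize(t3, sin(2 * pi * t3), n_points = 1001L)
  expect_lt(max(abs(tn3$values - sin(2 * pi * seq(0, 1, length.out = 1001)))),
            1e-3)
  expect_error(time_normalize(c(0, 0.2, 0.1), 1:3), "strictly increasing")
})

make_series <- function(time, fun_by_channel) {
  bc <- as.data.frame(lapply(fun_by_channel, function(f) f(time)))
  structure(list(time = time, by_category = bc),
            class = "decomposition_series")
}

const_series <- function(time, ext, mus, lig) {
  chans <- list()
  for (comp in c("med", "lat", "tot")) {
    chans[[paste0("external_", comp)]] <- local({
      v <- ext; function(t) rep(v, length(t))
    })
    chans[[paste0("muscle_", comp)]] <- local({
      v <- mus; function(t) rep(v, length(t))
    })
    chans[[paste0("ligament_", comp)]] <- local({
      v <- lig; function(t) rep(v, length(t))
    })
  }
  tot <- ext + mus + lig
  chans$f_med <- chans$f_lat <- chans$f_total <-
    local({ v <- tot; function(t) rep(v, length(t)) })
  make_series(time, chans)
}

default_events <- function(T) {
  c(hs_ipsi = 0, to_contra = 0.16 * T, hs_contra = 0.84 * T, to_ipsi = T)
}

test_that("constant loads give their literal percent split", {
  time <- seq(0, 0.6, by = 0.01)
  ser <- const_series(time, 40, 35, 25)
  ph <- phase_percent_contributions(ser, default_events(0.6))
  expect_identical(nrow(ph), 12L)
  expect_true(all(abs(ph$external - 40) < 1e-9))
  expect_true(all(abs(ph$muscle - 35) < 1e-9))
  expect_true(all(abs(ph$ligament - 25) < 1e-9))
  # negative contributions are preserved and still sum to 100
  ser2 <- const_series(time, -20, 90, 30)
  ph2 <- phase_percent_contributions(ser2, default_events(0.6))
  expect_true(all(abs(ph2$external + 20) < 1e-9))
  expect_true(all(abs(ph2$external + ph2$muscle + ph2$ligament - 100) <
                    1e-9))
})

test_that("percent sums conserve 100 and match a dense-quadrature oracle", {
  withr::with_seed(47, {
    time <- seq(0, 0.66, by = 0.01)
    # smooth random series with consistent totals
    rand_chan <- function() {
      a <- runif(3, -50, 150)
      function(t) a[1L] + a[2L] * sin(pi * t / 0.66) +
        a[3L] * cos(2 * pi * t / 0.66)
    }
    chans <- list()
    for (comp in c("med", "lat", "tot")) {
      for (cat in c("external", "muscle", "ligament")) {
        chans[[paste0(cat, "_", comp)]] <- rand_chan()
      }
    }
    chans$f_med <- function(t) chans$external_med(t) + chans$muscle_med(t) +
      chans$ligament_med(t)
    chans$f_lat <- function(t) chans$external_lat(t) + chans$muscle_lat(t) +
      chans$ligament_lat(t)
    chans$f_total <- function(t) chans$external_tot(t) +
      chans$muscle_tot(t) + chans$ligament_tot(t)
    ser <- make_series(time, chans)
    ev <- default_events(0.66)
    ph <- phase_percent_contributions(ser, ev)
    expect_true(all(abs(ph$external + ph$muscle + ph$ligament - 100) <
                      1e-6))
    # dense-quadrature oracle on the same linear interpolant
    dense_pct <- function(cat_chan, tot_chan, w) {
      tt <- seq(w[1L], w[2L], length.out = 20001L)
      y1 <- approx(time, cat_chan, xout = tt)$y
      y2 <- approx(time, tot_chan, xout = tt)$y
      trap <- function(y) sum(diff(tt) * (head(y, -1) + tail(y, -1)) / 2)
      100 * trap(y1) / trap(y2)
    }
    wins <- list(whole_stance = c(0, 0.66),
                 single_support = c(ev[["to_contra"]], ev[["hs_contra"]]))
    for (ph_name in names(wins)) {
      got <- ph[ph$phase == ph_name & ph$compartment == "medial", ]
      want <- dense_pct(ser$by_category$external_med,
                        ser$by_category$f_med, wins[[ph_name]])
      expect_lt(abs(got$external - want) / max(1, abs(want)), 1e-6)
    }
  })
})

test_that("whole-stance integrals equal the sum of sub-phase integrals", {
  withr::with_seed(53, {
    time <- seq(0, 0.7, by = 0.01)
    y <- cumsum(rnorm(length(time)))
    ev <- default_events(0.7)
    whole <- kneeload:::integrate_interval(time, y, 0, 0.7)
    parts <- kneeload:::integrate_interval(time, y, 0, ev[["to_contra"]]) +
      kneeload:::integrate_interval(time, y, ev[["to_contra"]],
                                    ev[["hs_contra"]]) +
      kneeload:::integrate_interval(time, y, ev[["hs_contra"]], 0.7)
    expect_lt(abs(whole - parts), 1e-9 * max(1, abs(whole)))
  })
})

test_that("degenerate phases and bad events are rejected", {
  time <- seq(0, 0.6, by = 0.01)
  ser <- const_series(time, 0, 0, 0)
  expect_error(phase_percent_contributions(ser, default_events(0.6)),
               "degenerate phase")
  ser2 <- const_series(time, 40, 35, 25)
  expect_error(phase_percent_contributions(
    ser2, c(hs_ipsi = 0, to_contra = 0.5, hs_contra = 0.3, to_ipsi = 0.6)),
    "ordered")
  expect_error(phase_percent_contributions(
    ser2, c(hs_ipsi = 0, to_contra = 0.2, hs_contra = 0.5, to_ipsi = 0.9)),
    "time span")
})

test_that("normality test flags the pinned fixtures correctly", {
  withr::with_seed(59, {
    gauss <- rnorm(20)
    heavy <- exp(rnorm(20, sd = 1.5))
  })
  expect_gt(normality_test(gauss)$p, 0.05)
  expect_lt(normality_test(heavy)$p, 0.05)
  expect_error(normality_test(rep(1, 10)), "undefined test")
  expect_error(normality_test(c(1, 2)), "invalid input")
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  withr::with_seed(61, {
    for (rep in 1:200) {
      p <- runif(sample(1:20, 1))
      expect_identical(bh_adjust(p), bh_reference(p))
    }
  })
})

long_summary <- function(values, subjects, phase = "whole_stance",
                         compartment = "total") {
  do.call(rbind, lapply(c("external", "muscle", "ligament"), function(cat) {
    data.frame(subject_id = subjects, phase = phase,
               compartment = compartment, category = cat,
               percent = values[[cat]], stringsAsFactors = FALSE)
  }))
}

test_that("group comparison picks tests, adjusts p, and handles ties", {
  withr::with_seed(67, {
    base <- list(external = rnorm(20, 30, 3), muscle = rnorm(20, 45, 4),
                 ligament = rnorm(20, 25, 5))
  })
  subj <- sprintf("s%02d", 1:20)
  a <- long_summary(base, subj)
  # identical groups: zero mean difference, t statistic 0, raw p 1
  res_same <- compare_groups(a, a)
  t_rows <- res_same$test == "t"
  expect_true(any(t_rows))
  expect_true(all(abs(res_same$statistic[t_rows]) < 1e-12))
  expect_true(all(res_same$p_raw[t_rows] > 0.999))
  expect_true(all(res_same$p_raw > 0.9))
  expect_true(all(res_same$p_adj >= res_same$p_raw - 1e-15))
  expect_true(all(res_same$p_adj <= 1))
  # a 2 SD shift at n = 20/20 is detected after adjustment
  shifted <- lapply(base, function(v) v + 2 * sd(v))
  b <- long_summary(shifted, subj)
  res_shift <- compare_groups(a, b)
  expect_true(all(res_shift$p_adj < 0.001))
  expect_true(all(res_shift$significant))
  expect_error(compare_groups(a[0, ], b), "empty group")
})

test_that("non-normal samples are routed to the rank-sum test", {
  withr::with_seed(71, {
    heavy <- list(external = exp(rnorm(20, sd = 1.6)),
                  muscle = exp(rnorm(20, sd = 1.6)),
                  ligament = exp(rnorm(20, sd = 1.6)))
    norm <- list(external = rnorm(20), muscle = rnorm(20),
                 ligament = rnorm(20))
  })
  subj <- sprintf("s%02d", 1:20)
  res <- compare_groups(long_summary(heavy, subj), long_summary(norm, subj))
  expect_true(any(res$test == "rank"))
})

test_that("within-group category contrasts are paired", {
  withr::with_seed(73, {
    vals <- list(external = rnorm(15, 30, 2), muscle = rnorm(15, 45, 2),
                 ligament = rnorm(15, 25, 2))
  })
  subj <- sprintf("s%02d", 1:15)
  res <- category_contrasts(long_summary(vals, subj))
  expect_identical(nrow(res), 3L)
  expect_true(all(res$p_adj >= res$p_raw - 1e-15))
  # clearly separated categories are significant
  expect_true(res$significant[res$pair == "external_vs_muscle"])
})
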