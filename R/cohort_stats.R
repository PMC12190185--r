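#' Time-normalize a stance series onto a 0-100% grid
#'
#' Linear interpolation of one or more channels onto an evenly spaced grid
#' spanning the series' time range (endpoints preserved exactly). Used to
#' express all stance curves from 0% to 100% of the stance phase.
#'
#' @param time Strictly increasing time vector (s), length >= 2.
#' @param values Numeric vector, matrix, or data frame of channels sampled
#'   at `time`.
#' @param n_points Grid size (default 101: 0%, 1%, ..., 100%).
#' @return List with `percent` (0-100 grid) and `values` (resampled, same
#'   shape as the input channels).
#' @export
time_normalize <- function(time, values, n_points = 101L) {
  if (length(time) < 2L) {
    stop("invalid input: need at least 2 samples", call. = FALSE)
  }
  if (is.unsorted(time, strictly = TRUE)) {
    stop("invalid input: time must be strictly increasing", call. = FALSE)
  }
  grid <- seq(time[1L], time[length(time)], length.out = n_points)
  one <- function(y) approx(time, y, xout = grid, rule = 2)$y
  if (is.null(dim(values))) {
    out <- one(values)
  } else {
    out <- apply(as.matrix(values), 2L, one)
    colnames(out) <- colnames(values)
  }
  list(percent = seq(0, 100, length.out = n_points), values = out)
}

# Trapezoidal integral of a sampled channel over [t0, t1], with linear
# interpolation at the interval boundaries so that adjacent phases add
# exactly to their union.
integrate_interval <- function(time, y, t0, t1) {
  if (t1 <= t0) return(0)
  inside <- time > t0 & time < t1
  knots <- c(t0, time[inside], t1)
  vals <- approx(time, y, xout = knots, rule = 2)$y
  sum(diff(knots) * (utils::head(vals, -1L) + utils::tail(vals, -1L)) / 2)
}

stance_phases <- c("whole_stance", "first_double_support",
                   "single_support", "second_double_support")

phase_windows <- function(events) {
  need <- c("hs_ipsi", "to_contra", "hs_contra", "to_ipsi")
  if (!all(need %in% names(events))) {
    stop("invalid input: events must name ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  e <- events[need]
  if (is.unsorted(e, strictly = TRUE)) {
    stop("invalid input: events must be ordered hs_ipsi < to_contra < ",
         "hs_contra < to_ipsi", call. = FALSE)
  }
  list(whole_stance = c(e[["hs_ipsi"]], e[["to_ipsi"]]),
       first_double_support = c(e[["hs_ipsi"]], e[["to_contra"]]),
       single_support = c(e[["to_contra"]], e[["hs_contra"]]),
       second_double_support = c(e[["hs_contra"]], e[["to_ipsi"]]))
}

#' Percent contributions per stance phase and compartment
#'
#' The percent contribution of force category `c` to compartment `X` over
#' phase `P` is the integral ratio
#' `100 * integral_P(C_X,c dt) / integral_P(F_X dt)`: the category's share
#' of the compartment's load-time integral. Within each
#' (phase, compartment) the three category percentages sum to 100 by
#' construction; individual values may be negative (a category that unloads
#' the compartment) or exceed 100.
#'
#' @param series A `"decomposition_series"` from [decompose_trial()].
#' @param events Named event times (s): `hs_ipsi`, `to_contra`,
#'   `hs_contra`, `to_ipsi`; must lie within the series' time span.
#' @param mode `"integral"` (default, the ratio above) or `"mean_ratio"`
#'   (mean of per-frame ratios; unstable when the compartment load nears
#'   zero, provided for comparison).
#' @return Data frame with one row per phase x compartment and columns
#'   `phase`, `compartment`, `external`, `muscle`, `ligament` (percent).
#' @export
phase_percent_contributions <- function(series, events,
                                        mode = c("integral", "mean_ratio")) {
  mode <- match.arg(mode)
  wins <- phase_windows(events)
  tt <- series$time
  if (min(tt) - 1e-9 > wins$whole_stance[1L] ||
      max(tt) + 1e-9 < wins$whole_stance[2L]) {
    stop("invalid input: events outside the trial's time span",
         call. = FALSE)
  }
  bc <- series$by_category
  comps <- c(total = "tot", medial = "med", lateral = "lat")
  totals <- c(total = "f_total", medial = "f_med", lateral = "f_lat")
  rows <- list()
  for (ph in names(wins)) {
    w <- wins[[ph]]
    for (cn in names(comps)) {
      f_tot <- bc[[totals[[cn]]]]
      denom <- integrate_interval(tt, f_tot, w[1L], w[2L])
      peak <- max(abs(f_tot))
      if (peak == 0 || abs(denom) < 1e-9 * peak * (w[2L] - w[1L])) {
        stop("degenerate phase: compartment load-time integral is ",
             "numerically zero in ", ph, call. = FALSE)
      }
      pct <- vapply(c("external", "muscle", "ligament"), function(cat) {
        ch <- bc[[paste0(cat, "_", comps[[cn]])]]
        if (mode == "integral") {
          100 * integrate_interval(tt, ch, w[1L], w[2L]) / denom
        } else {
          sel <- tt >= w[1L] & tt <= w[2L]
          mean(100 * ch[sel] / f_tot[sel])
        }
      }, 0)
      rows[[length(rows) + 1L]] <- data.frame(
        phase = ph, compartment = cn,
        external = pct[["external"]], muscle = pct[["muscle"]],
        ligament = pct[["ligament"]], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Shapiro-Wilk normality test
#'
#' Thin wrapper with the sample-size and degeneracy contract made explicit.
#'
#' @param x Numeric sample, 3 <= n <= 5000, non-constant.
#' @return List with `W` and `p`.
#' @export
normality_test <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 3L || length(x) > 5000L) {
    stop("invalid input: Shapiro-Wilk requires 3 <= n <= 5000",
         call. = FALSE)
  }
  if (diff(range(x)) == 0) {
    stop("undefined test: sample is constant", call. = FALSE)
  }
  ht <- shapiro.test(x)
  list(W = unname(ht$statistic), p = ht$p.value)
}

#' Benjamini-Hochberg adjusted p values
#'
#' Step-up false-discovery-rate adjustment over one declared family.
#'
#' @param p Vector of raw p values.
#' @return Adjusted p values (same order).
#' @export
bh_adjust <- function(p) p.adjust(p, method = "BH")

choose_test <- function(x, y, alpha = 0.05) {
  normal <- function(v) {
    if (length(v) < 3L || diff(range(v)) == 0) return(FALSE)
    shapiro.test(v)$p.value > alpha
  }
  if (normal(x) && normal(y)) "t" else "rank"
}

#' Compare percent contributions between two groups
#'
#' One contrast per (phase, compartment, category): the independent t-test
#' when both groups pass Shapiro-Wilk normality at `alpha`, otherwise the
#' rank-sum (Mann-Whitney) test. Raw p values are Benjamini-Hochberg
#' adjusted within the declared family (all contrasts of one call by
#' default, or per compartment with `family = "compartment"`, mirroring one
#' family per output table).
#'
#' @param summaries_a,summaries_b Subject-level percent-contribution tables
#'   (long format: columns `phase`, `compartment`, `category`, `percent`,
#'   one row per subject x contrast), e.g. from [subject_summaries()].
#' @param alpha Significance level on adjusted p (default 0.05).
#' @param family `"all"` or `"compartment"`.
#' @param labels Group labels for the output columns.
#' @return Data frame with one row per contrast: group means and SDs, test
#'   used, statistic, raw and adjusted p, significance flag.
#' @export
compare_groups <- function(summaries_a, summaries_b, alpha = 0.05,
                           family = c("all", "compartment"),
                           labels = c("healthy", "koa")) {
  family <- match.arg(family)
  for (s in list(summaries_a, summaries_b)) {
    if (!nrow(s)) stop("invalid input: empty group", call. = FALSE)
  }
  keys <- unique(summaries_a[, c("phase", "compartment", "category")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    k <- keys[i, ]
    pick <- function(s) s$percent[s$phase == k$phase &
                                    s$compartment == k$compartment &
                                    s$category == k$category]
    x <- pick(summaries_a); y <- pick(summaries_b)
    if (length(x) < 2L || length(y) < 2L) {
      stop("invalid input: need >= 2 subjects per group per contrast",
           call. = FALSE)
    }
    test <- choose_test(x, y, alpha)
    ht <- if (test == "t") {
      t.test(x, y, var.equal = TRUE)
    } else {
      suppressWarnings(wilcox.test(x, y, exact = FALSE))
    }
    data.frame(phase = k$phase, compartment = k$compartment,
               category = k$category, test = test,
               statistic = unname(ht$statistic), p_raw = ht$p.value,
               mean_a = mean(x), sd_a = sd(x),
               mean_b = mean(y), sd_b = sd(y),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (family == "all") {
    out$p_adj <- bh_adjust(out$p_raw)
  } else {
    out$p_adj <- NA_real_
    for (cn in unique(out$compartment)) {
      sel <- out$compartment == cn
      out$p_adj[sel] <- bh_adjust(out$p_raw[sel])
    }
  }
  out$significant <- out$p_adj < alpha
  names(out)[names(out) == "mean_a"] <- paste0("mean_", labels[1L])
  names(out)[names(out) == "sd_a"] <- paste0("sd_", labels[1L])
  names(out)[names(out) == "mean_b"] <- paste0("mean_", labels[2L])
  names(out)[names(out) == "sd_b"] <- paste0("sd_", labels[2L])
  rownames(out) <- NULL
  out
}

#' Within-group pairwise category contrasts
#'
#' For each (phase, compartment) within one group, compares the percent
#' contributions of each pair of force categories across subjects using the
#' paired t-test when the paired differences pass Shapiro-Wilk normality at
#' `alpha`, otherwise the Wilcoxon signed-rank test (the paired design is
#' where the signed-rank form applies). Benjamini-Hochberg adjustment over
#' the family of all pairs in the call.
#'
#' @param summaries Subject-level long table (see [compare_groups()]).
#' @param alpha Significance level (default 0.05).
#' @return Data frame of contrasts with raw and adjusted p values.
#' @export
category_contrasts <- function(summaries, alpha = 0.05) {
  pairs <- list(c("external", "muscle"), c("external", "ligament"),
                c("muscle", "ligament"))
  keys <- unique(summaries[, c("phase", "compartment")])
  rows <- list()
  for (i in seq_len(nrow(keys))) {
    k <- keys[i, ]
    sub <- summaries[summaries$phase == k$phase &
                       summaries$compartment == k$compartment, ]
    for (pr in pairs) {
      x <- sub$percent[sub$category == pr[1L]][order(
        sub$subject_id[sub$category == pr[1L]])]
      y <- sub$percent[sub$category == pr[2L]][order(
        sub$subject_id[sub$category == pr[2L]])]
      d <- x - y
      test <- if (length(d) >= 3L && diff(range(d)) > 0 &&
                    shapiro.test(d)$p.value > alpha) "t" else "rank"
      ht <- if (test == "t") {
        t.test(x, y, paired = TRUE)
      } else {
        suppressWarnings(wilcox.test(x, y, paired = TRUE, exact = FALSE))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        phase = k$phase, compartment = k$compartment,
        pair = paste(pr, collapse = "_vs_"), test = test,
        statistic = unname(ht$statistic), p_raw = ht$p.value,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p_raw)
  out$significant <- out$p_adj < alpha
  rownames(out) <- NULL
  out
}
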