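#' LOESS-smooth a metric profile
#'
#' Locally weighted quadratic regression (tricube kernel, no robustness
#' iterations) evaluated at the input positions; the default span of 0.1
#' means each local fit uses the nearest 10% of windows. Missing values are
#' dropped before fitting and interpolated by the fit.
#'
#' @param positions Window midpoints (bp).
#' @param values Metric values (may contain `NA`).
#' @param span LOESS span, fraction of points in each local fit.
#' @return Smoothed values at `positions`.
#' @export
loess_smooth <- function(positions, values, span = 0.1) {
  ok <- !is.na(values)
  n_ok <- sum(ok)
  if (n_ok < max(5, ceiling(span * length(values)))) {
    stop("too few defined points (", n_ok, ") to smooth with span ", span)
  }
  # a quadratic local fit needs >= 5 points in every neighbourhood; raise
  # the effective span when the profile is short (coarse windows)
  span <- max(span, min(1, 5 / n_ok))
  # statistics = "none": only fitted values are needed, and the standard-
  # error bookkeeping emits spurious NaN warnings at small spans
  fit <- stats::loess(values[ok] ~ positions[ok], span = span, degree = 2,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct",
                                                     statistics = "none"))
  as.numeric(stats::predict(fit, newdata = positions))
}

#' Magnitude, breadth and area of a diversity dip
#'
#' `magnitude` is the baseline diversity (the non-selected population's
#' level) minus the minimum of the smoothed selected-population profile.
#' `breadth` is the distance between the first positions left and right of
#' the selected site where the profile recovers to half the baseline,
#' divided by 100 kb. `area = magnitude * breadth / 2`, the area of the
#' triangle those two numbers describe.
#'
#' @param positions Profile positions (bp), increasing.
#' @param values Smoothed diversity profile of the selected population.
#' @param baseline Baseline diversity level (> 0), e.g. the mean smoothed
#'   diversity of the non-selected population.
#' @param sel_pos Selected-site position (bp).
#' @return A list with `magnitude`, `breadth`, `area` and `flag` (`"ok"`,
#'   `"no_dip"` when the profile never falls below half the baseline, or
#'   `"censored"` when it never recovers within the profile).
#' @export
peak_metrics <- function(positions, values, baseline, sel_pos) {
  if (!is.finite(baseline) || baseline <= 0) stop("`baseline` must be > 0")
  ok <- !is.na(values)
  positions <- positions[ok]; values <- values[ok]
  magnitude <- baseline - min(values)
  half <- baseline / 2
  flag <- "ok"
  if (min(values) >= half) {
    breadth <- 0
    flag <- "no_dip"
  } else {
    right <- positions >= sel_pos
    ri <- which(right & values >= half)
    li <- which(!right & values >= half)
    rpos <- if (length(ri)) positions[min(ri)] else { flag <- "censored"; max(positions) }
    lpos <- if (length(li)) positions[max(li)] else { flag <- "censored"; min(positions) }
    breadth <- (rpos - lpos) / 1e5
  }
  list(magnitude = magnitude, breadth = breadth,
       area = magnitude * breadth / 2, flag = flag)
}

#' Area under a metric peak around the selected site
#'
#' Trapezoidal integral of the profile over `sel_pos +/- halfwidth`
#' (endpoints linearly interpolated), divided by 100 000 so that typical
#' values are of order 1. The profile must cover the interval.
#'
#' @inheritParams peak_metrics
#' @param halfwidth Half-width of the integration interval in bp.
#' @return Scaled area (a single number).
#' @export
area_under_peak <- function(positions, values, sel_pos, halfwidth = 1e5) {
  ok <- !is.na(values)
  positions <- positions[ok]; values <- values[ok]
  lo <- sel_pos - halfwidth; hi <- sel_pos + halfwidth
  if (length(positions) < 2 || min(positions) > lo || max(positions) < hi) {
    stop("profile does not cover [sel_pos - halfwidth, sel_pos + halfwidth]")
  }
  inside <- positions > lo & positions < hi
  xs <- c(lo, positions[inside], hi)
  ys <- c(stats::approx(positions, values, lo)$y,
          values[inside],
          stats::approx(positions, values, hi)$y)
  sum(diff(xs) * (utils::head(ys, -1) + utils::tail(ys, -1)) / 2) / 1e5
}

#' Persistence of sweep signals after fixation
#'
#' Summarizes per-replicate peak statistics collected at several sampling
#' delays (`tau_post`): the median across replicates of the per-replicate
#' maxima, and quartiles of the peak areas. As `tau_post` grows the
#' population drifts back to mutation-drift equilibrium and both decay
#' toward the neutral distribution -- more slowly at higher ploidy, whose
#' coalescent clock ticks at `1/(N k)`.
#'
#' @param tbl A data frame with columns `tau_post`, `max_value` and `area`
#'   (one row per replicate per delay).
#' @return A tibble with one row per `tau_post`: `n`, `median_max`,
#'   `median_area`, `area_q25`, `area_q75`.
#' @export
persistence_curve <- function(tbl) {
  if (length(unique(tbl$tau_post)) < 2) {
    stop("need >= 2 distinct tau_post values")
  }
  parts <- split(tbl, tbl$tau_post)
  out <- lapply(parts, function(d) {
    tibble::tibble(
      tau_post = d$tau_post[1],
      n = nrow(d),
      median_max = stats::median(d$max_value, na.rm = TRUE),
      median_area = stats::median(d$area, na.rm = TRUE),
      area_q25 = stats::quantile(d$area, 0.25, na.rm = TRUE, names = FALSE),
      area_q75 = stats::quantile(d$area, 0.75, na.rm = TRUE, names = FALSE))
  })
  do.call(rbind, out)
}

#' Coefficient of variation of per-replicate maxima, with bootstrap interval
#'
#' `CV = sd / mean` over the per-replicate maximum values of a metric; the
#' uncertainty interval comes from resampling `block` replicates with
#' replacement `n_resample` times and taking the 2.5% / 97.5% quantiles of
#' the resampled CVs.
#'
#' @param values Per-replicate maxima (length >= 2).
#' @param n_resample Number of bootstrap iterations.
#' @param block Number of replicates per bootstrap draw.
#' @return A list with `cv`, `lower`, `upper`.
#' @export
cv_bootstrap <- function(values, n_resample = 1000, block = 200) {
  values <- values[!is.na(values)]
  if (length(values) < 2) stop("need >= 2 values")
  if (mean(values) == 0) stop("mean of values is 0; CV undefined")
  cv <- stats::sd(values) / mean(values)
  boot <- vapply(seq_len(n_resample), function(i) {
    v <- sample(values, block, replace = TRUE)
    stats::sd(v) / mean(v)
  }, numeric(1))
  q <- stats::quantile(boot, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  list(cv = cv, lower = q[1], upper = q[2])
}

#' Peak summary for one replicate
#'
#' Smooths the selected population's diversity profile, estimates the
#' baseline from the non-selected population (mean of its smoothed profile
#' by default, median as an option), and computes the dip metrics plus, for
#' each additional metric column, the signed maximum and the area under the
#' peak within 100 kb of the selected site.
#'
#' @param tbl A [window_table()]-style tibble (columns `mid`, `pi_sel`,
#'   `pi_neu`, plus any metric columns named in `metrics`).
#' @param sel_pos Selected-site position (bp).
#' @param span LOESS span.
#' @param metrics Character vector of metric columns to summarize by
#'   max/area-under-peak (missing columns are skipped).
#' @param baseline_stat `"mean"` or `"median"` of the smoothed non-selected
#'   profile.
#' @return A one-row tibble: `magnitude`, `breadth`, `area`, `flag`,
#'   `baseline`, `pi_min`, and `<metric>_max` / `<metric>_auc` columns.
#' @export
peak_summary <- function(tbl, sel_pos, span = 0.1,
                         metrics = c("tajd_neg_sel", "fst_std"),
                         baseline_stat = c("mean", "median")) {
  baseline_stat <- match.arg(baseline_stat)
  sm_sel <- loess_smooth(tbl$mid, tbl$pi_sel, span)
  sm_neu <- loess_smooth(tbl$mid, tbl$pi_neu, span)
  baseline <- if (baseline_stat == "mean") mean(sm_neu, na.rm = TRUE) else
    stats::median(sm_neu, na.rm = TRUE)
  pm <- peak_metrics(tbl$mid, sm_sel, baseline, sel_pos)
  out <- tibble::tibble(
    magnitude = pm$magnitude, breadth = pm$breadth, area = pm$area,
    flag = pm$flag, baseline = baseline, pi_min = min(sm_sel, na.rm = TRUE))
  for (mc in intersect(metrics, names(tbl))) {
    sm <- loess_smooth(tbl$mid, tbl[[mc]], span)
    out[[paste0(mc, "_max")]] <- max(sm, na.rm = TRUE)
    out[[paste0(mc, "_auc")]] <-
      area_under_peak(tbl$mid, sm, sel_pos)
  }
  out
}
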