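#' Tumor growth parameters linking ER suppression to growth rate
#'
#' Growth follows the per-animal exponential model
#' `log10 V(t) = log10 V0 + integral of slope(t)`, with instantaneous slope
#' `b0 - bkill * (1 - E(t)/e0)^gamma` (log10 mm^3 per day). At full ER
#' (`E = e0`) this reduces exactly to the exponential model
#' `log10(V) = a + b * t`; `bkill` is the maximal regression rate
#' attributable to complete ER loss and `gamma` shapes the link.
#'
#' @param b0 Intrinsic growth rate, log10(mm^3)/day.
#' @param bkill Maximal kill rate at full ER suppression (>= 0),
#'   log10(mm^3)/day.
#' @param gamma Shape of the ER-to-growth link (> 0).
#' @return An object of class `growth_params`.
#' @export
growth_params <- function(b0, bkill = 0, gamma = 1) {
  if (!is.numeric(b0) || length(b0) != 1 || !is.finite(b0))
    stop("'b0' must be a single finite number (log10 mm^3/day)")
  if (!is.numeric(bkill) || length(bkill) != 1 || bkill < 0)
    stop("'bkill' must be a single non-negative number")
  if (!is.numeric(gamma) || length(gamma) != 1 || gamma <= 0)
    stop("'gamma' must be a single positive number")
  structure(list(b0 = b0, bkill = bkill, gamma = gamma),
            class = "growth_params")
}

#' @export
print.growth_params <- function(x, ...) {
  cat(sprintf("Tumor growth: b0 = %.4g log10/day, bkill = %.4g, gamma = %.3g\n",
              x$b0, x$bkill, x$gamma))
  invisible(x)
}

#' Simulate a tumor volume trajectory driven by an ER time course
#'
#' Integrates `d log10 V / dt = b0 - bkill * (1 - E(t)/e0)^gamma` by
#' trapezoidal quadrature on a fine grid, with `E(t)` linearly interpolated
#' from the supplied ER course (times in hours; held at its last value
#' beyond the course).
#'
#' @param params A [growth_params()] object.
#' @param er_course An `er_time_course` data frame (`time_h`, `rel_er`)
#'   covering the study window, or `NULL` for a drug-free animal.
#' @param days Study days at which to report volumes (>= 0).
#' @param v0 Baseline volume at day 0, mm^3 (> 0).
#' @param e0 Baseline ER level used for normalization (default 1).
#' @param grid_step Integration step in days.
#' @return A `tumor_volume_series` data frame with columns `day`,
#'   `volume_mm3`.
#' @examples
#' gp <- growth_params(b0 = 0.02)
#' simulate_tumor(gp, NULL, days = c(0, 7, 14), v0 = 200)
#' @export
simulate_tumor <- function(params, er_course, days, v0, e0 = 1,
                           grid_step = 0.25) {
  stopifnot(inherits(params, "growth_params"))
  if (!is.numeric(v0) || length(v0) != 1 || v0 <= 0)
    stop("'v0' must be a single positive volume (mm^3)")
  if (any(days < 0)) stop("'days' must be non-negative")
  days <- sort(unique(days))
  e_at <- function(t_days) {
    if (is.null(er_course)) return(rep(e0, length(t_days)))
    stats::approx(er_course$time_h / 24, er_course$rel_er, xout = t_days,
                  rule = 2)$y
  }
  grid <- sort(unique(c(seq(0, max(days, grid_step), by = grid_step), days)))
  supp <- pmax(0, pmin(1, 1 - e_at(grid) / e0))
  slope <- params$b0 - params$bkill * supp^params$gamma
  dt <- diff(grid)
  cum <- c(0, cumsum(dt * (slope[-1] + slope[-length(slope)]) / 2))
  log10v <- log10(v0) + cum[match(days, grid)]
  out <- data.frame(day = days, volume_mm3 = 10^log10v)
  class(out) <- c("tumor_volume_series", "data.frame")
  out
}

#' Per-animal exponential growth-rate fit
#'
#' Ordinary least squares of `log10(volume)` on study day, after replacing
#' volumes below the floor (15 mm^3 by default, the caliper reliability
#' limit) with the floor value.
#'
#' @param series A data frame with columns `day` and `volume_mm3`, or a
#'   numeric vector of days if `volume` is supplied.
#' @param volume Optional numeric vector of volumes (mm^3).
#' @param floor Minimum volume substituted before the log transform.
#' @return An object of class `growth_fit` with elements `a` (log10 mm^3
#'   intercept), `b` (log10 mm^3/day slope), `sigma` (residual SD) and the
#'   underlying `lm`.
#' @examples
#' fit_growth_rate(data.frame(day = c(0, 7, 14), volume_mm3 = c(200, 276, 381)))
#' @export
fit_growth_rate <- function(series, volume = NULL, floor = 15) {
  if (is.data.frame(series)) {
    day <- series$day
    volume <- series$volume_mm3
  } else {
    day <- series
  }
  keep <- is.finite(day) & is.finite(volume)
  day <- day[keep]; volume <- volume[keep]
  if (length(day) < 3) stop("at least 3 measurement days are required")
  if (any(volume <= 0)) stop("volumes must be positive")
  lv <- log10(pmax(volume, floor))
  fit <- stats::lm(lv ~ day)
  co <- stats::coef(fit)
  structure(list(a = unname(co[1]), b = unname(co[2]),
                 sigma = suppressWarnings(summary(fit)$sigma), n = length(day), lm = fit,
                 floor = floor),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf(
    "Exponential growth fit: log10(V) = %.4g + %.4g * day (residual SD %.3g, n = %d, floor %g mm^3)\n",
    x$a, x$b, x$sigma, x$n, x$floor))
  invisible(x)
}

#' @export
coef.growth_fit <- function(object, ...) c(a = object$a, b = object$b)

#' @export
predict.growth_fit <- function(object, days, ...) {
  data.frame(day = days, volume_mm3 = 10^(object$a + object$b * days))
}

#' Percent tumor-volume change from baseline
#'
#' `(V_end - V_baseline) / V_baseline * 100`, using the day-0 volume as
#' baseline and the last measured volume as endpoint.
#'
#' @inheritParams fit_growth_rate
#' @return Percent change (unbounded; negative values indicate regression).
#' @export
percent_tv_change <- function(series, volume = NULL) {
  if (is.data.frame(series)) {
    day <- series$day
    volume <- series$volume_mm3
  } else {
    day <- series
  }
  o <- order(day)
  day <- day[o]; volume <- volume[o]
  v0 <- volume[1]
  if (!is.finite(v0) || v0 <= 0) stop("baseline volume must be positive")
  (volume[length(volume)] - v0) / v0 * 100
}

# Per-animal endpoint/baseline volume ratios for one arm.
# V_end is taken at the requested end day; an animal missing that day is
# carried forward from its last observation when that observation lies
# within `locf_window` days of the end, otherwise it is excluded.
endpoint_ratios <- function(arm_df, end_day, locf_window = 7) {
  stopifnot(all(c("animal", "day", "volume_mm3") %in% names(arm_df)))
  out <- c(); dropped <- character()
  for (a in unique(arm_df$animal)) {
    d <- arm_df[arm_df$animal == a, , drop = FALSE]
    d <- d[order(d$day), , drop = FALSE]
    v0 <- d$volume_mm3[d$day == min(d$day)][1]
    at_end <- d$volume_mm3[d$day == end_day]
    if (length(at_end) == 0) {
      last_day <- max(d$day[d$day <= end_day])
      if (end_day - last_day <= locf_window) {
        at_end <- d$volume_mm3[d$day == last_day][1]
      } else {
        dropped <- c(dropped, as.character(a))
        next
      }
    }
    out <- c(out, stats::setNames(at_end[1] / v0, as.character(a)))
  }
  if (length(dropped) > 0)
    message("excluded animal(s) with no measurement within ", locf_window,
            " days of study end: ", paste(dropped, collapse = ", "))
  out
}

# last day with measurements in both arms
common_end_day <- function(treated, control) {
  common <- intersect(unique(treated$day), unique(control$day))
  if (length(common) == 0) stop("treated and control share no measurement days")
  max(common)
}

#' Tumor growth inhibition from geometric-mean volume change
#'
#' Compares the geometric mean over animals of `V_end / V_baseline` between
#' a treated and a control arm:
#' `TGI% = 100 * (1 - (GM_T - 1) / (GM_C - 1))` for a growing control
#' (`GM_C > 1`). A static treated arm (`GM_T = 1`) gives 100%; values above
#' 100% indicate regression and are reported unclipped. A non-growing
#' control makes TGI undefined and the result is flagged.
#'
#' @param treated,control Data frames with columns `animal`, `day`,
#'   `volume_mm3` for one arm each.
#' @param end_day Endpoint day; defaults to the last day measured in both
#'   arms. Animals missing the end day are carried forward only from within
#'   `locf_window` days, otherwise excluded with a message.
#' @param locf_window Carry-forward window in days.
#' @return An object of class `tgi_result` with per-animal percent changes,
#'   geometric means, `tgi` (percent), `defined` flag, the one-tailed Welch
#'   `p` versus control, and the endpoint day used.
#' @export
tgi <- function(treated, control, end_day = NULL, locf_window = 7) {
  if (nrow(treated) == 0 || nrow(control) == 0)
    stop("both arms must be non-empty")
  if (is.null(end_day)) end_day <- common_end_day(treated, control)
  rt <- endpoint_ratios(treated, end_day, locf_window)
  rc <- endpoint_ratios(control, end_day, locf_window)
  if (length(rt) == 0 || length(rc) == 0)
    stop("no usable animals at the endpoint day in one of the arms")
  gm_t <- exp(mean(log(rt)))
  gm_c <- exp(mean(log(rc)))
  defined <- gm_c > 1
  tgi_pct <- if (defined) 100 * (1 - (gm_t - 1) / (gm_c - 1)) else NA_real_
  p <- if (length(rt) >= 2 && length(rc) >= 2)
    tryCatch(welch_one_tailed(log(rt), log(rc)), error = function(e) NA_real_)
  else NA_real_
  structure(list(
    pct_change_treated = 100 * (rt - 1),
    pct_change_control = 100 * (rc - 1),
    gm_treated = gm_t, gm_control = gm_c,
    gm_pct_change_treated = 100 * (gm_t - 1),
    gm_pct_change_control = 100 * (gm_c - 1),
    tgi = tgi_pct, defined = defined, p = p, end_day = end_day),
    class = "tgi_result")
}

#' @export
print.tgi_result <- function(x, ...) {
  cat(sprintf("TGI at day %g: ", x$end_day))
  if (x$defined) cat(sprintf("%.1f%%", x$tgi))
  else cat("undefined (control geometric-mean change <= 1)")
  cat(sprintf("\n  GM V_end/V_base: treated %.3f, control %.3f\n",
              x$gm_treated, x$gm_control))
  if (is.finite(x$p))
    cat(sprintf("  one-tailed Welch p (treated < control, log change): %.4g\n", x$p))
  invisible(x)
}

# one-tailed Welch p for H1: mean(x) < mean(y)
welch_one_tailed <- function(x, y) {
  stats::t.test(x, y, alternative = "less", var.equal = FALSE)$p.value
}

#' One-tailed unequal-variance test of log tumor-volume change
#'
#' Welch t test on `log(V_end / V_baseline)` per animal, one-tailed with
#' alternative "treated grows less than control".
#'
#' @inheritParams tgi
#' @param alternative `"less"` (default, treatment reduces growth) or
#'   `"two.sided"`.
#' @return A list with `p`, the t `statistic`, Welch `df`, per-arm log
#'   changes, and the endpoint day.
#' @export
compare_to_vehicle <- function(treated, control, end_day = NULL,
                               locf_window = 7, alternative = c("less", "two.sided")) {
  alternative <- match.arg(alternative)
  if (is.null(end_day)) end_day <- common_end_day(treated, control)
  lt <- log(endpoint_ratios(treated, end_day, locf_window))
  lc <- log(endpoint_ratios(control, end_day, locf_window))
  if (length(lt) < 2 || length(lc) < 2)
    stop("at least 2 animals per arm are required")
  tt <- stats::t.test(lt, lc, alternative = alternative, var.equal = FALSE)
  list(p = tt$p.value, statistic = unname(tt$statistic),
       df = unname(tt$parameter), log_change_treated = lt,
       log_change_control = lc, end_day = end_day,
       alternative = alternative)
}
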