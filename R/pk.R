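#' Oral dose regimen
#'
#' Describes repeated oral dosing of a compound: the dose in mg/kg, the
#' dosing interval in hours, the number of doses, and the molecular weight
#' used to convert mass concentrations to molar units.
#'
#' @param dose Dose in mg/kg (>= 0; 0 encodes a vehicle arm).
#' @param interval Dosing interval in hours (> 0). Default 24 (once daily).
#' @param n_doses Number of doses administered (>= 1).
#' @param molecular_weight Molecular weight in g/mol, used to express plasma
#'   concentrations in nmol/L.
#' @return An object of class `dose_regimen`.
#' @examples
#' qd10 <- dose_regimen(dose = 10, interval = 24, n_doses = 14)
#' @export
dose_regimen <- function(dose, interval = 24, n_doses = 1,
                         molecular_weight = 452) {
  if (!is.numeric(dose) || length(dose) != 1 || is.na(dose) || dose < 0)
    stop("'dose' must be a single non-negative number (mg/kg)")
  if (!is.numeric(interval) || length(interval) != 1 || interval <= 0)
    stop("'interval' must be a single positive number of hours")
  if (!is.numeric(n_doses) || length(n_doses) != 1 || n_doses < 1 ||
      n_doses != round(n_doses))
    stop("'n_doses' must be a positive integer")
  if (!is.numeric(molecular_weight) || molecular_weight <= 0)
    stop("'molecular_weight' must be positive (g/mol)")
  structure(list(dose = dose, interval = interval, n_doses = as.integer(n_doses),
                 molecular_weight = molecular_weight),
            class = "dose_regimen")
}

#' @export
print.dose_regimen <- function(x, ...) {
  cat(sprintf("Dose regimen: %g mg/kg every %g h x %d dose(s) (MW %g g/mol)\n",
              x$dose, x$interval, x$n_doses, x$molecular_weight))
  invisible(x)
}

#' One-compartment oral PK parameters
#'
#' Parameters of a one-compartment model with first-order absorption and
#' elimination, expressed per kg body weight so concentrations follow from
#' mg/kg doses directly.
#'
#' @param ka First-order absorption rate constant (1/h, > 0).
#' @param ke First-order elimination rate constant (1/h, > 0). `ka == ke` is
#'   permitted; the analytic limit form is used.
#' @param vd_over_f Apparent volume of distribution V/F in L/kg (> 0).
#' @param fu Free (unbound) fraction in plasma, in (0, 1].
#' @return An object of class `pk_params`.
#' @export
pk_params <- function(ka, ke, vd_over_f, fu = 1) {
  if (!is.numeric(ka) || length(ka) != 1 || ka <= 0)
    stop("'ka' must be a single positive rate (1/h)")
  if (!is.numeric(ke) || length(ke) != 1 || ke <= 0)
    stop("'ke' must be a single positive rate (1/h)")
  if (!is.numeric(vd_over_f) || length(vd_over_f) != 1 || vd_over_f <= 0)
    stop("'vd_over_f' must be a single positive volume (L/kg)")
  if (!is.numeric(fu) || length(fu) != 1 || fu <= 0 || fu > 1)
    stop("'fu' must be a free fraction in (0, 1]")
  structure(list(ka = ka, ke = ke, vd_over_f = vd_over_f, fu = fu),
            class = "pk_params")
}

#' @export
print.pk_params <- function(x, ...) {
  cat(sprintf("PK parameters: ka = %.4g /h, ke = %.4g /h (t1/2 = %.3g h), V/F = %.4g L/kg, fu = %.4g\n",
              x$ka, x$ke, log(2) / x$ke, x$vd_over_f, x$fu))
  invisible(x)
}

# Single-dose unit concentration profile (mg/L) at post-dose times tau (h).
# Uses the analytic ka -> ke limit when the rates coincide.
single_dose_conc <- function(tau, dose, ka, ke, vd) {
  out <- numeric(length(tau))
  pos <- tau >= 0
  t0 <- tau[pos]
  if (abs(ka - ke) < 1e-10 * max(ka, ke)) {
    out[pos] <- dose * ka * t0 * exp(-ka * t0) / vd
  } else {
    out[pos] <- dose * ka / (vd * (ka - ke)) * (exp(-ke * t0) - exp(-ka * t0))
  }
  out
}

#' Predict plasma concentration under repeat oral dosing
#'
#' Evaluates the one-compartment first-order absorption model with linear
#' superposition over doses and converts to nmol/L via the regimen's
#' molecular weight. Free concentration is `fu` times total.
#'
#' @param params A [pk_params()] object.
#' @param regimen A [dose_regimen()] object.
#' @param times Times in hours since the first dose (>= 0).
#' @return A `concentration_series` data frame with columns `time_h`,
#'   `conc_nM` (total) and `free_nM`.
#' @examples
#' pk <- pk_params(ka = 1, ke = 0.1, vd_over_f = 5, fu = 0.01)
#' predict_concentration(pk, dose_regimen(10, 24, 3), times = c(1, 2, 24, 48))
#' @export
predict_concentration <- function(params, regimen, times) {
  stopifnot(inherits(params, "pk_params"), inherits(regimen, "dose_regimen"))
  if (any(!is.finite(times)) || any(times < 0))
    stop("'times' must be finite and non-negative (hours)")
  conc <- numeric(length(times))
  for (k in seq_len(regimen$n_doses)) {
    conc <- conc + single_dose_conc(times - (k - 1) * regimen$interval,
                                    regimen$dose, params$ka, params$ke,
                                    params$vd_over_f)
  }
  total_nM <- conc * 1e6 / regimen$molecular_weight  # mg/L -> nmol/L
  out <- data.frame(time_h = times, conc_nM = total_nM,
                    free_nM = params$fu * total_nM)
  class(out) <- c("concentration_series", "data.frame")
  out
}

#' Free plasma concentration from total
#'
#' @param total Total concentration(s), nmol/L.
#' @param fu Free fraction in (0, 1].
#' @return Free concentration(s), `fu * total`.
#' @export
free_concentration <- function(total, fu) {
  if (!is.numeric(fu) || length(fu) != 1 || fu <= 0 || fu > 1)
    stop("'fu' must be a free fraction in (0, 1]")
  if (any(total < 0, na.rm = TRUE)) stop("'total' concentrations must be >= 0")
  total * fu
}

#' Free-concentration function of time for a regimen
#'
#' Returns a vectorized function `f(t_hours) -> free nmol/L`, convenient as
#' the exposure input of [simulate_er()].
#'
#' @inheritParams predict_concentration
#' @return A function of time (hours) returning free concentration (nmol/L).
#' @export
free_conc_fn <- function(params, regimen) {
  force(params); force(regimen)
  dose_times <- (seq_len(regimen$n_doses) - 1) * regimen$interval
  scale <- params$fu * 1e6 / regimen$molecular_weight
  fn <- function(t) {
    t <- pmax(t, 0)
    tot <- numeric(length(t))
    for (d0 in dose_times) {
      tot <- tot + single_dose_conc(t - d0, regimen$dose, params$ka,
                                    params$ke, params$vd_over_f)
    }
    tot * scale
  }
  # tag so simulate_er() can use the compiled exposure evaluator
  attr(fn, "pk_spec") <- list(pk = params, regimen = regimen)
  fn
}

#' Fit one-compartment oral PK parameters to a concentration series
#'
#' Least squares on the log-concentration scale (stabilizing the wide
#' dynamic range of plasma profiles). `ka`, `ke` and `vd_over_f` are
#' estimated; `fu` is not identifiable from total concentrations and is
#' carried through from `fu`.
#'
#' @param series Data frame with columns `time_h` and `conc_nM` (total
#'   concentration). At least 4 distinct timepoints with positive
#'   concentrations are required.
#' @param regimen The [dose_regimen()] under which the data were collected.
#' @param fu Free fraction to attach to the returned parameters.
#' @param start Optional named list of starting values (`ka`, `ke`,
#'   `vd_over_f`).
#' @return An object of class `pk_fit` with elements `params`
#'   ([pk_params()]), `converged`, `sigma` (residual SD of log
#'   concentration), `fitted`, `residuals` and `data`.
#' @export
fit_pk <- function(series, regimen, fu = 1, start = NULL) {
  stopifnot(is.data.frame(series), inherits(regimen, "dose_regimen"))
  if (!all(c("time_h", "conc_nM") %in% names(series)))
    stop("'series' needs columns 'time_h' and 'conc_nM'")
  keep <- is.finite(series$time_h) & is.finite(series$conc_nM)
  series <- series[keep, , drop = FALSE]
  if (length(unique(series$time_h)) < 4)
    stop("at least 4 distinct timepoints are required to fit PK")
  if (all(series$conc_nM <= 0)) stop("no drug signal: all concentrations are zero")
  obs <- series[series$conc_nM > 0, , drop = FALSE]
  lobs <- log(obs$conc_nM)

  if (is.null(start)) {
    # crude initials: terminal slope for ke, faster rate for ka, volume from peak
    start <- list(ka = 1, ke = 0.1, vd_over_f = 1)
    tl <- obs$time_h >= stats::median(obs$time_h)
    if (sum(tl) >= 2) {
      sl <- stats::coef(stats::lm(log(conc_nM) ~ time_h, data = obs[tl, ]))[2]
      if (is.finite(sl) && sl < 0) start$ke <- min(max(-sl, 1e-3), 50)
    }
    start$ka <- min(max(5 * start$ke, 0.2), 50)
    peak <- max(obs$conc_nM)
    pred1 <- max(predict_concentration(
      pk_params(start$ka, start$ke, 1, 1), regimen,
      seq(0, max(obs$time_h), length.out = 200))$conc_nM)
    if (pred1 > 0 && peak > 0) start$vd_over_f <- min(max(pred1 / peak, 1e-3), 1e3)
  }

  obj <- function(lp) {
    p <- exp(lp)
    pr <- predict_concentration(pk_params(p[1], p[2], p[3], 1), regimen,
                                obs$time_h)$conc_nM
    if (any(!is.finite(pr)) || any(pr <= 0)) return(1e10)
    sum((log(pr) - lobs)^2)
  }
  fit <- stats::nlminb(log(c(start$ka, start$ke, start$vd_over_f)), obj,
                       lower = log(c(1e-3, 1e-3, 1e-3)),
                       upper = log(c(100, 100, 1e3)))
  p <- exp(fit$par)
  # absorption/elimination flip-flop: report the faster rate as ka
  if (p[2] > p[1]) p <- c(p[2], p[1], p[3] * p[2] / p[1])
  params <- pk_params(p[1], p[2], p[3], fu)
  pred <- predict_concentration(params, regimen, obs$time_h)$conc_nM
  resid <- log(pred) - lobs
  converged <- fit$convergence == 0 && all(is.finite(resid))
  structure(list(params = params, converged = converged,
                 sigma = stats::sd(resid), objective = fit$objective,
                 fitted = pred, residuals = resid, data = obs,
                 regimen = regimen),
            class = "pk_fit")
}

#' @export
print.pk_fit <- function(x, ...) {
  cat("One-compartment oral PK fit (log-scale least squares)\n")
  print(x$params)
  cat(sprintf("  residual SD (log conc): %.4g; converged: %s\n",
              x$sigma, x$converged))
  invisible(x)
}

#' @export
coef.pk_fit <- function(object, ...) {
  with(object$params, c(ka = ka, ke = ke, vd_over_f = vd_over_f, fu = fu))
}

#' @export
predict.pk_fit <- function(object, times = NULL, regimen = NULL, ...) {
  if (is.null(times)) times <- object$data$time_h
  if (is.null(regimen)) regimen <- object$regimen
  predict_concentration(object$params, regimen, times)
}

#' @export
residuals.pk_fit <- function(object, ...) object$residuals
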