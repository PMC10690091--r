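#' ER turnover (indirect response) parameters
#'
#' Parameters of the stimulation-of-loss turnover model for ER protein:
#' \deqn{dE/dt = k_{out} e_0 - k_{out} (1 + S_{max} C_u / (SC_{50} + C_u)) E}
#' Basal synthesis is implied as `ksyn = kout * e0`, so the drug-free steady
#' state is `e0` (ER level as fraction of untreated baseline). Drug free
#' concentration `Cu` multiplies the degradation rate through an Emax term:
#' maximal fold-stimulation `1 + smax`, half-maximal at `Cu = sc50`.
#'
#' @param kout Basal first-order degradation rate, 1/h (> 0). Basal protein
#'   half-life is `log(2)/kout`.
#' @param smax Maximal fold-stimulation of degradation (>= 0, unitless).
#' @param sc50 Free drug concentration giving half-maximal stimulation,
#'   nmol/L (> 0). This is the in vivo degradation IC50.
#' @param e0 Baseline ER level; 1 after normalization to untreated control.
#' @return An object of class `er_params`.
#' @examples
#' er_params(kout = log(2) / 3, smax = 9, sc50 = 0.4)
#' @export
er_params <- function(kout, smax, sc50, e0 = 1) {
  if (!is.numeric(kout) || length(kout) != 1 || kout <= 0)
    stop("'kout' must be a single positive rate (1/h)")
  if (!is.numeric(smax) || length(smax) != 1 || smax < 0)
    stop("'smax' must be a single non-negative number")
  if (!is.numeric(sc50) || length(sc50) != 1 || sc50 <= 0)
    stop("'sc50' must be a single positive concentration (nmol/L)")
  if (!is.numeric(e0) || length(e0) != 1 || e0 <= 0)
    stop("'e0' must be a single positive baseline level")
  structure(list(kout = kout, smax = smax, sc50 = sc50, e0 = e0),
            class = "er_params")
}

#' @export
print.er_params <- function(x, ...) {
  cat(sprintf(
    "ER turnover: kout = %.4g /h (basal t1/2 = %.3g h), smax = %.4g, sc50 = %.4g nM, e0 = %g\n",
    x$kout, log(2) / x$kout, x$smax, x$sc50, x$e0))
  invisible(x)
}

# fold-stimulation of degradation at free concentration cu
stim_fold <- function(params, cu) 1 + params$smax * cu / (params$sc50 + cu)

#' Simulate ER protein level under a free-concentration profile
#'
#' Integrates the stimulation-of-loss turnover ODE from `E(0) = e0` given a
#' time-varying free drug concentration.
#'
#' @param params An [er_params()] object.
#' @param free_conc_fn Function of time (hours) returning free concentration
#'   (nmol/L, >= 0). A single number is accepted and treated as constant.
#' @param times Non-negative times (hours) at which to report the solution.
#' @param rtol,atol Integrator tolerances passed to [deSolve::lsoda()].
#' @return An `er_time_course` data frame with columns `time_h`, `rel_er`.
#' @examples
#' p <- er_params(kout = log(2) / 3, smax = 9, sc50 = 0.4)
#' simulate_er(p, function(t) rep(2, length(t)), times = c(0, 4, 8, 24))
#' @export
simulate_er <- function(params, free_conc_fn, times, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "er_params"))
  if (any(!is.finite(times)) || any(times < 0))
    stop("'times' must be finite and non-negative (hours)")
  ot <- sort(unique(c(0, times)))

  cparms <- NULL
  if (is.numeric(free_conc_fn) && length(free_conc_fn) == 1) {
    if (!is.finite(free_conc_fn) || free_conc_fn < 0)
      stop("a constant exposure must be a finite non-negative concentration")
    cparms <- c(params$kout, params$smax, params$sc50, params$e0,
                1, 1, free_conc_fn, 1, -1)
  } else if (!is.null(sp <- attr(free_conc_fn, "pk_spec"))) {
    cparms <- c(params$kout, params$smax, params$sc50, params$e0,
                sp$pk$ka, sp$pk$ke,
                sp$regimen$dose / sp$pk$vd_over_f * sp$pk$fu * 1e6 /
                  sp$regimen$molecular_weight,
                sp$regimen$interval, sp$regimen$n_doses)
  } else if (!is.function(free_conc_fn)) {
    stop("'free_conc_fn' must be a function of time or a single constant")
  }

  if (!is.null(cparms)) {
    sol <- deSolve::lsoda(c(E = params$e0), ot, func = "serd_derivs",
                          parms = cparms, dllname = "serdpd",
                          initfunc = "serd_initmod",
                          rtol = rtol, atol = atol, maxsteps = 1e5)
  } else {
    rhs <- function(t, y, parms) {
      cu <- free_conc_fn(t)
      if (!is.finite(cu) || cu < 0)
        stop("free_conc_fn returned an invalid concentration at t = ", t)
      list(params$kout * params$e0 - params$kout * stim_fold(params, cu) * y[1])
    }
    sol <- deSolve::lsoda(c(E = params$e0), ot, rhs, parms = NULL,
                          rtol = rtol, atol = atol, maxsteps = 1e5)
  }
  if (attr(sol, "istate")[1] < 0)
    stop("ER turnover ODE integration failed; istate = ", attr(sol, "istate")[1])
  lev <- sol[match(times, ot), "E"]
  out <- data.frame(time_h = times, rel_er = as.numeric(lev))
  class(out) <- c("er_time_course", "data.frame")
  out
}

#' Fraction of ER suppressed at steady state under constant exposure
#'
#' Under constant free concentration the turnover model settles at
#' `E = e0 / (1 + smax*Cu/(sc50+Cu))`; the suppressed fraction is
#' `1 - 1/(1 + smax*Cu/(sc50+Cu))`, bounded by `smax/(1+smax)`.
#'
#' @param params An [er_params()] object.
#' @param free_conc Constant free concentration(s), nmol/L (>= 0).
#' @return Suppressed fraction(s) in `[0, smax/(1+smax)]`.
#' @export
steady_state_suppression <- function(params, free_conc) {
  stopifnot(inherits(params, "er_params"))
  if (any(free_conc < 0, na.rm = TRUE)) stop("'free_conc' must be >= 0")
  1 - 1 / stim_fold(params, free_conc)
}

#' Estimate protein half-life from a decay time course
#'
#' Fits `log(level)` on time by ordinary least squares over the declining
#' phase (all points from the global maximum onward; at least 3 required)
#' and returns `log(2)/|slope|`.
#'
#' @param course An `er_time_course` data frame (columns `time_h`,
#'   `rel_er`), or a numeric vector of times if `level` is given.
#' @param level Optional numeric vector of levels matching `course` times.
#' @return An object of class `halflife_fit` with elements `half_life`
#'   (hours), `slope` (1/h), `sigma`, `n_used`, and the fitted `lm`.
#' @examples
#' tc <- simulate_decay_course(3, times = c(0, 1, 2, 4, 8, 12), noise_model(seed = 1))
#' estimate_half_life(tc)
#' @export
estimate_half_life <- function(course, level = NULL) {
  if (is.data.frame(course)) {
    times <- course$time_h
    level <- course$rel_er
  } else {
    times <- course
  }
  if (length(times) != length(level)) stop("times and levels differ in length")
  keep <- is.finite(times) & is.finite(level)
  times <- times[keep]; level <- level[keep]
  if (any(level <= 0)) stop("levels must be positive for log-linear decay fitting")
  if (length(times) < 3) stop("at least 3 timepoints are required")
  o <- order(times)
  times <- times[o]; level <- level[o]
  i0 <- which.max(level)
  if (length(times) - i0 + 1 < 3)
    stop("no measurable decay: fewer than 3 points from the maximum onward")
  td <- times[i0:length(times)]; ld <- level[i0:length(level)]
  fit <- stats::lm(log(ld) ~ td)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope >= 0)
    stop("no measurable decay: non-negative log-linear slope")
  structure(list(half_life = log(2) / abs(slope), slope = slope,
                 sigma = suppressWarnings(summary(fit)$sigma), n_used = length(td), lm = fit),
            class = "halflife_fit")
}

#' @export
print.halflife_fit <- function(x, ...) {
  cat(sprintf("Half-life estimate: %.4g h (slope %.4g /h, %d points used)\n",
              x$half_life, x$slope, x$n_used))
  invisible(x)
}

#' @export
coef.halflife_fit <- function(object, ...) {
  c(half_life = object$half_life, slope = object$slope)
}

#' Fit the ER degradation PK/PD model across dose arms
#'
#' Least-squares fit of `(kout, smax, sc50)` (with `e0` fixed at 1 by
#' normalization) to ER time courses from several dose arms, using the
#' one-compartment PK model to supply the free-concentration driver for
#' each arm. Parameters are optimized on the log scale.
#'
#' @param er Data frame with columns `arm`, `time_h`, `rel_er`.
#' @param pk A [pk_params()] object shared by all arms.
#' @param regimens Named list mapping each arm label to a [dose_regimen()]
#'   (or `NULL` / dose 0 for vehicle). At least two non-vehicle dose levels
#'   are required for `sc50` to be identifiable.
#' @param start Optional [er_params()] starting values.
#' @param rtol ODE tolerance used during fitting.
#' @return An object of class `er_pkpd_fit` with elements `params`
#'   ([er_params()]), `se_log` (approximate SEs of log parameters),
#'   `converged`, `sse`, `n_obs`, plus the inputs.
#' @export
fit_er_pkpd <- function(er, pk, regimens, start = NULL, rtol = 1e-6) {
  stopifnot(is.data.frame(er), inherits(pk, "pk_params"), is.list(regimens))
  if (!all(c("arm", "time_h", "rel_er") %in% names(er)))
    stop("'er' needs columns 'arm', 'time_h', 'rel_er'")
  arms <- unique(as.character(er$arm))
  if (!all(arms %in% names(regimens)))
    stop("missing regimen for arm(s): ",
         paste(setdiff(arms, names(regimens)), collapse = ", "))
  doses <- vapply(regimens[arms], function(r) if (is.null(r)) 0 else r$dose, 0)
  if (length(unique(doses[doses > 0])) < 2)
    stop("sc50 is unidentifiable: at least 2 distinct non-vehicle dose levels are required")

  # per-arm exposure functions and observation grids
  arm_dat <- lapply(arms, function(a) {
    d <- er[er$arm == a, , drop = FALSE]
    reg <- regimens[[a]]
    fn <- if (is.null(reg) || reg$dose == 0) 0 else free_conc_fn(pk, reg)
    ut <- sort(unique(d$time_h))
    list(obs = d, fn = fn, ut = ut, idx = match(d$time_h, ut))
  })

  if (is.null(start)) start <- er_params(kout = 0.2, smax = 5, sc50 = 1)
  obj <- function(lp) {
    p <- er_params(exp(lp[1]), exp(lp[2]), exp(lp[3]), e0 = 1)
    sse <- 0
    for (ad in arm_dat) {
      pred <- tryCatch(
        simulate_er(p, ad$fn, ad$ut, rtol = rtol, atol = 1e-8)$rel_er,
        error = function(e) NULL)
      if (is.null(pred) || any(!is.finite(pred))) return(1e10)
      sse <- sse + sum((pred[ad$idx] - ad$obs$rel_er)^2)
    }
    sse
  }
  lp0 <- log(c(start$kout, start$smax, start$sc50))
  # Nelder-Mead copes with the residual integrator noise in the objective;
  # a bounded quasi-Newton pass then polishes the optimum
  nm <- stats::optim(lp0, obj, method = "Nelder-Mead",
                     control = list(maxit = 500, reltol = 1e-10))
  fit <- stats::nlminb(nm$par, obj,
                       lower = log(c(1e-3, 1e-2, 1e-4)),
                       upper = log(c(10, 1e3, 1e4)))
  converged <- nm$convergence == 0 || fit$convergence == 0
  if (fit$objective > nm$value) {
    fit$par <- nm$par
    fit$objective <- nm$value
  }
  # approximate SEs from the Hessian of the SSQ surface
  se_log <- rep(NA_real_, 3)
  hess <- tryCatch(stats::optimHess(fit$par, obj), error = function(e) NULL)
  n_obs <- nrow(er)
  if (!is.null(hess)) {
    s2 <- fit$objective / max(n_obs - 3, 1)
    cov <- tryCatch(2 * s2 * solve(hess), error = function(e) NULL)
    if (!is.null(cov)) {
      dg <- diag(cov)
      se_log <- ifelse(dg > 0, sqrt(pmax(dg, 0)), NA_real_)
    }
  }
  p <- exp(fit$par)
  structure(list(params = er_params(p[1], p[2], p[3], e0 = 1),
                 se_log = stats::setNames(se_log, c("kout", "smax", "sc50")),
                 converged = converged, sse = fit$objective,
                 n_obs = n_obs, pk = pk, regimens = regimens, data = er),
            class = "er_pkpd_fit")
}

#' @export
print.er_pkpd_fit <- function(x, ...) {
  cat("ER degradation PK/PD fit (stimulation-of-loss indirect response)\n")
  print(x$params)
  cat(sprintf("  SSE = %.4g over %d observations; converged: %s\n",
              x$sse, x$n_obs, x$converged))
  if (any(is.finite(x$se_log)))
    cat(sprintf("  approx. SE (log scale): kout %.3g, smax %.3g, sc50 %.3g\n",
                x$se_log[1], x$se_log[2], x$se_log[3]))
  invisible(x)
}

#' @export
coef.er_pkpd_fit <- function(object, ...) {
  with(object$params, c(kout = kout, smax = smax, sc50 = sc50))
}

#' Average ER suppression over a steady-state dosing interval
#'
#' Doses the turnover model to steady state (at least 10 elimination
#' half-lives of dosing) and returns the time average of `1 - E(t)/e0`
#' over the final dosing interval, the quantity the efficacy analysis
#' relates to antitumor effect.
#'
#' @param params An [er_params()] object.
#' @param pk A [pk_params()] object.
#' @param regimen A [dose_regimen()]; its `n_doses` is extended if needed
#'   to reach steady state.
#' @param n_grid Quadrature grid size over the final interval.
#' @return Mean suppressed fraction over the interval, in
#'   `[0, smax/(1+smax)]`.
#' @examples
#' er <- er_params(kout = log(2) / 3, smax = 9, sc50 = 0.4)
#' pk <- pk_params(ka = 1, ke = log(2) / 5, vd_over_f = 5, fu = 0.01)
#' average_suppression(er, pk, dose_regimen(10, 24, 14))
#' @export
average_suppression <- function(params, pk, regimen, n_grid = 201) {
  stopifnot(inherits(params, "er_params"), inherits(pk, "pk_params"),
            inherits(regimen, "dose_regimen"))
  if (regimen$dose == 0) return(0)
  n_ss <- ceiling(10 * log(2) / pk$ke / regimen$interval) + 1
  reg <- regimen
  reg$n_doses <- max(regimen$n_doses, n_ss)
  t_last <- (reg$n_doses - 1) * reg$interval
  grid <- seq(t_last, t_last + reg$interval, length.out = n_grid)
  course <- simulate_er(params, free_conc_fn(pk, reg), grid, rtol = 1e-8)
  supp <- 1 - course$rel_er / params$e0
  # trapezoidal time average over the interval
  dt <- diff(grid)
  sum(dt * (supp[-1] + supp[-length(supp)]) / 2) / (grid[length(grid)] - grid[1])
}
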