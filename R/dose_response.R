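#' Normalize proliferation-assay counts to a growth scale
#'
#' Live counts (total minus dead) are rescaled so that the day-0 plate mean
#' defines 0 (no net growth) and the untreated day-7 mean defines 1 (full
#' growth): `response = (treated - day0) / (untreated7 - day0)`. Values
#' below 0 indicate net cell loss (cytotoxicity) and are retained.
#'
#' @param day0_mean Mean live count of the day-0 control plate.
#' @param untreated_mean Mean live count of the untreated endpoint wells
#'   (day 7, or day 6 for lines assayed earlier).
#' @param treated Live counts of treated wells.
#' @param conc Optional concentrations matching `treated`; if supplied the
#'   result is a data frame with columns `conc` and `response`.
#' @return Normalized responses (vector), or a data frame if `conc` given.
#' @examples
#' normalize_growth(1000, 5000, treated = c(1000, 3000, 5000))
#' @export
normalize_growth <- function(day0_mean, untreated_mean, treated, conc = NULL) {
  if (any(c(day0_mean, untreated_mean, treated) < 0, na.rm = TRUE))
    stop("counts must be non-negative")
  if (untreated_mean <= day0_mean)
    stop("no growth window: untreated endpoint mean must exceed the day-0 mean")
  response <- (treated - day0_mean) / (untreated_mean - day0_mean)
  if (is.null(conc)) return(response)
  if (length(conc) != length(treated))
    stop("'conc' and 'treated' must have the same length")
  data.frame(conc = conc, response = response)
}

#' Fit a four-parameter logistic concentration-response curve
#'
#' Least-squares 4PL fit on the log10-concentration axis:
#' `y = bottom + (top - bottom) / (1 + 10^(hill * (log10(c) - log10(ic50))))`
#' so the response runs from `top` at vanishing drug to `bottom` at
#' saturation for `hill > 0`. The IC50 is the curve midpoint (relative
#' IC50); `pic50 = -log10(ic50)` with concentrations in mol/L.
#'
#' @param conc Concentrations in mol/L (> 0); at least 6 points spanning at
#'   least 2 logs.
#' @param response Normalized responses from [normalize_growth()].
#' @param degenerate_range Response range below which the curve is declared
#'   flat and no IC50 is reported.
#' @return An object of class `fourpl_fit` with elements `top`, `bottom`,
#'   `ic50` (mol/L), `hill`, `pic50`, `converged`, `degenerate`,
#'   `in_range` (IC50 inside the tested ladder), `sigma` and the data.
#' @examples
#' conc <- 10^seq(-11, -6.5, by = 0.5)
#' resp <- 0 + (1 - 0) / (1 + (conc / 1e-8))
#' fit_4pl(conc, resp)
#' @export
fit_4pl <- function(conc, response, degenerate_range = 0.1) {
  keep <- is.finite(conc) & is.finite(response)
  conc <- conc[keep]; response <- response[keep]
  if (any(conc <= 0)) stop("concentrations must be positive (mol/L)")
  if (length(conc) < 6) stop("at least 6 concentrations are required")
  lc <- log10(conc)
  if (diff(range(lc)) < 2) stop("concentrations must span at least 2 logs")
  if (diff(range(response)) < degenerate_range) {
    return(structure(list(top = mean(response), bottom = mean(response),
                          ic50 = NA_real_, hill = NA_real_, pic50 = NA_real_,
                          converged = FALSE, degenerate = TRUE,
                          in_range = NA, sigma = stats::sd(response),
                          data = data.frame(conc = conc, response = response)),
                     class = "fourpl_fit"))
  }
  top0 <- max(response); bot0 <- min(response)
  half <- (top0 + bot0) / 2
  lic0 <- lc[which.min(abs(response - half))]
  df <- data.frame(lc = lc, y = response)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ bottom + (top - bottom) / (1 + 10^(hill * (lc - lic50))),
      data = df,
      start = list(top = top0, bottom = bot0, lic50 = lic0, hill = 1),
      lower = c(-Inf, -Inf, min(lc) - 4, 0.1),
      upper = c(Inf, Inf, max(lc) + 4, 10),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(top = NA_real_, bottom = NA_real_, ic50 = NA_real_,
                          hill = NA_real_, pic50 = NA_real_, converged = FALSE,
                          degenerate = FALSE, in_range = NA, sigma = NA_real_,
                          data = df), class = "fourpl_fit"))
  }
  co <- stats::coef(fit)
  if (co["top"] < co["bottom"]) {  # reparameterize so top >= bottom
    tmp <- co["top"]; co["top"] <- co["bottom"]; co["bottom"] <- tmp
    co["hill"] <- -co["hill"]
  }
  ic50 <- 10^co[["lic50"]]
  structure(list(top = co[["top"]], bottom = co[["bottom"]], ic50 = ic50,
                 hill = co[["hill"]], pic50 = -log10(ic50),
                 converged = TRUE, degenerate = FALSE,
                 in_range = co[["lic50"]] >= min(lc) && co[["lic50"]] <= max(lc),
                 sigma = summary(fit)$sigma, nls = fit,
                 data = data.frame(conc = conc, response = response)),
            class = "fourpl_fit")
}

#' @export
print.fourpl_fit <- function(x, ...) {
  if (x$degenerate) {
    cat("4PL fit: degenerate (flat response); no IC50 reported\n")
    return(invisible(x))
  }
  if (!x$converged) {
    cat("4PL fit: did not converge\n")
    return(invisible(x))
  }
  cat(sprintf("4PL fit: pIC50 = %.3f (IC50 = %.3g mol/L), hill = %.3g\n",
              x$pic50, x$ic50, x$hill))
  cat(sprintf("  top = %.3g, bottom = %.3g; IC50 %s the tested range\n",
              x$top, x$bottom, if (isTRUE(x$in_range)) "inside" else "outside"))
  invisible(x)
}

#' @export
coef.fourpl_fit <- function(object, ...) {
  c(top = object$top, bottom = object$bottom, ic50 = object$ic50,
    hill = object$hill, pic50 = object$pic50)
}

#' @export
predict.fourpl_fit <- function(object, conc = NULL, ...) {
  if (object$degenerate) stop("degenerate fit: no curve to predict from")
  if (is.null(conc)) conc <- object$data$conc
  object$bottom + (object$top - object$bottom) /
    (1 + 10^(object$hill * (log10(conc) + object$pic50)))
}

#' @export
plot.fourpl_fit <- function(x, ...) {
  graphics::plot(log10(x$data$conc), x$data$response,
                 xlab = "log10 concentration (mol/L)",
                 ylab = "normalized growth", ...)
  if (!x$degenerate && x$converged) {
    lc <- seq(min(log10(x$data$conc)), max(log10(x$data$conc)), length.out = 200)
    graphics::lines(lc, predict(x, conc = 10^lc))
  }
  invisible(x)
}

#' Bottom-of-curve value at saturating drug
#'
#' @param fit A non-degenerate [fit_4pl()] result.
#' @return A list with `bottom` and `cytotoxic` (TRUE when the plateau is
#'   below zero, i.e. net cell loss).
#' @export
bottom_of_curve <- function(fit) {
  stopifnot(inherits(fit, "fourpl_fit"))
  if (fit$degenerate || !fit$converged)
    stop("bottom-of-curve requires a converged, non-degenerate 4PL fit")
  # tolerance keeps a numerically-zero plateau from being called cytotoxic
  list(bottom = fit$bottom, cytotoxic = fit$bottom < -1e-6)
}

#' pIC50 from IC50 and back
#'
#' `pic50 = -log10(ic50)` with IC50 in mol/L.
#'
#' @param ic50 IC50 in mol/L (> 0).
#' @return The pIC50 value.
#' @export
pic50 <- function(ic50) {
  if (any(ic50 <= 0, na.rm = TRUE)) stop("'ic50' must be positive (mol/L)")
  -log10(ic50)
}

#' @rdname pic50
#' @param p pIC50 value.
#' @return `ic50_from_pic50`: the IC50 in mol/L.
#' @export
ic50_from_pic50 <- function(p) 10^(-p)
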