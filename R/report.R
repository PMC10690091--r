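#' Classify a model's drug sensitivity from its tumor-volume change
#'
#' A model is called sensitive when its percent change from baseline is at
#' most 100% (i.e. the tumor less than doubled under treatment), the single
#' documented threshold rule; anything above 100% is insensitive.
#'
#' @param pct_change Percent tumor-volume change(s) from baseline.
#' @return Character vector `"sensitive"` / `"insensitive"`.
#' @examples
#' classify_sensitivity(c(-30, 80, 150))
#' @export
classify_sensitivity <- function(pct_change) {
  if (any(!is.finite(pct_change))) stop("'pct_change' must be finite")
  ifelse(pct_change <= 100, "sensitive", "insensitive")
}

#' Waterfall ordering of model responses
#'
#' Sorts models by percent tumor-volume change in descending order (worst
#' responders first, as plotted), breaking ties lexicographically by model
#' id, and annotates each with its sensitivity class.
#'
#' @param responses Data frame with columns `model` and `pct_change`
#'   (additional columns are preserved).
#' @return The sorted, annotated data frame with class `waterfall`.
#' @export
waterfall <- function(responses) {
  stopifnot(is.data.frame(responses), nrow(responses) >= 1,
            all(c("model", "pct_change") %in% names(responses)))
  o <- order(-responses$pct_change, as.character(responses$model))
  out <- responses[o, , drop = FALSE]
  out$sensitivity <- classify_sensitivity(out$pct_change)
  rownames(out) <- NULL
  class(out) <- c("waterfall", "data.frame")
  out
}

#' @export
plot.waterfall <- function(x, ...) {
  cols <- ifelse(x$sensitivity == "sensitive", "steelblue", "firebrick")
  graphics::barplot(x$pct_change, names.arg = x$model, las = 2, col = cols,
                    ylab = "% tumor volume change from baseline", ...)
  graphics::abline(h = 100, lty = 2)
  invisible(x)
}

#' Cross-agent sensitivity proportions in a cohort
#'
#' Given per-model sensitivity calls for two agents, tabulates the fraction
#' of models sensitive to each agent and the dual-sensitive,
#' dual-insensitive and discordant fractions (exhaustive and mutually
#' exclusive, summing to 1).
#'
#' @param sensitive_a,sensitive_b Logical vectors (same models, same order).
#' @param agents Labels of the two agents.
#' @return A list with per-agent `sensitive_fraction` and the four joint
#'   class fractions.
#' @export
cohort_summary <- function(sensitive_a, sensitive_b,
                           agents = c("agent_a", "agent_b")) {
  if (length(sensitive_a) != length(sensitive_b))
    stop("sensitivity vectors must have equal length")
  n <- length(sensitive_a)
  if (n == 0) stop("empty cohort")
  joint <- c(both = mean(sensitive_a & sensitive_b),
             only_a = mean(sensitive_a & !sensitive_b),
             only_b = mean(!sensitive_a & sensitive_b),
             neither = mean(!sensitive_a & !sensitive_b))
  list(sensitive_fraction = stats::setNames(
         c(mean(sensitive_a), mean(sensitive_b)), agents),
       joint_fractions = joint, n_models = n)
}

#' Combination benefit over the best monotherapy
#'
#' A combination arm is called beneficial when it both (a) beats the best
#' monotherapy arm on the one-tailed Welch test of log tumor-volume change
#' at level `alpha`, and (b) has a lower geometric-mean percent volume
#' change. Best monotherapy is the mono arm with the lowest geometric-mean
#' percent change; ties break toward the endocrine-therapy arm when one is
#' named.
#'
#' @param volumes Volume table (`animal`, `arm`, `day`, `volume_mm3`)
#'   containing all arms of one study.
#' @param combo_arm Label of the combination arm.
#' @param mono_arms Labels of the monotherapy arms.
#' @param vehicle_arm Label of the vehicle arm (must be present).
#' @param endocrine_arm Optional mono arm preferred on ties.
#' @param alpha Significance level (default 0.05).
#' @return A list with `benefit` (logical), `p` (combo vs best mono),
#'   `best_mono`, per-arm geometric-mean percent changes, and the TGI of
#'   each arm versus vehicle.
#' @export
combination_benefit <- function(volumes, combo_arm, mono_arms, vehicle_arm,
                                endocrine_arm = NULL, alpha = 0.05) {
  arms_present <- unique(volumes$arm)
  need <- c(combo_arm, mono_arms, vehicle_arm)
  if (!all(need %in% arms_present))
    stop("arm(s) missing from the volume table: ",
         paste(setdiff(need, arms_present), collapse = ", "))
  arm_df <- function(a) volumes[volumes$arm == a, , drop = FALSE]
  veh <- arm_df(vehicle_arm)
  gm_pct <- vapply(c(mono_arms, combo_arm), function(a) {
    tgi(arm_df(a), veh)$gm_pct_change_treated
  }, 0)
  mono_gm <- gm_pct[mono_arms]
  best <- mono_arms[mono_gm == min(mono_gm)]
  if (length(best) > 1 && !is.null(endocrine_arm) && endocrine_arm %in% best)
    best <- endocrine_arm
  best <- best[1]
  cmp <- compare_to_vehicle(arm_df(combo_arm), arm_df(best))
  benefit <- cmp$p < alpha && gm_pct[combo_arm] < gm_pct[best]
  tgi_vs_vehicle <- vapply(c(mono_arms, combo_arm),
                           function(a) tgi(arm_df(a), veh)$tgi, 0)
  list(benefit = benefit, p = cmp$p, best_mono = best,
       gm_pct_change = gm_pct, tgi_vs_vehicle = tgi_vs_vehicle,
       alpha = alpha)
}

#' Run the full synthetic-study pipeline from a config file
#'
#' Reads a declarative YAML config (arms, truth, noise, cohort, alpha),
#' simulates the study, fits the ER degradation PK/PD model, computes TGI
#' and the one-tailed Welch test for every dose arm versus vehicle,
#' simulates the PDX-like cohort and builds its waterfall, and writes all
#' tables as TSV plus a plain-text run log. Outputs contain no timestamps,
#' so a fixed seed regenerates byte-identical files.
#'
#' @param config_file Path to the YAML config (see
#'   `system.file("extdata", "demo_study.yaml", package = "serdpd")`).
#' @param out_dir Output directory (created if absent).
#' @param seed Integer seed overriding the config's seed.
#' @return Invisibly, a list with the bundle, PK/PD fit, TGI table,
#'   waterfall and cohort summary.
#' @export
run_pipeline <- function(config_file, out_dir, seed = NULL) {
  cfg <- yaml::read_yaml(config_file)
  st <- cfg$study
  mw <- if (is.null(st$molecular_weight)) 452 else st$molecular_weight
  interval <- if (is.null(st$interval_h)) 24 else st$interval_h
  arms <- lapply(st$arms, function(dose) {
    if (dose == 0) NULL else dose_regimen(dose, interval, 1, mw)
  })
  design <- study_design(arms, n_per_arm = st$n_per_arm,
                         enrollment_volume_range =
                           unlist(st$enrollment_volume_range),
                         duration_days = st$duration_days)
  tr <- cfg$truth
  truth <- ground_truth(
    pk = do.call(pk_params, tr$pk),
    er = do.call(er_params, tr$er),
    growth = do.call(growth_params, tr$growth))
  if (is.null(seed)) seed <- if (is.null(cfg$seed)) 1 else cfg$seed
  noise <- noise_model(volume_cv = cfg$noise$volume_cv,
                       conc_cv = cfg$noise$conc_cv,
                       er_cv = cfg$noise$er_cv,
                       seed = seed)
  alpha <- if (is.null(cfg$alpha)) 0.05 else cfg$alpha

  bundle <- simulate_study(design, truth, noise)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_study_bundle(bundle, file.path(out_dir, "bundle"))

  # ER degradation PK/PD fit on the simulated ER courses
  regimens <- lapply(design$arms, cover_duration,
                     duration_days = design$duration_days)
  pkpd <- fit_er_pkpd(bundle$er, truth$pk, regimens)

  # efficacy statistics per dose arm versus vehicle
  doses <- vapply(design$arms, function(r) if (is.null(r)) 0 else r$dose, 0)
  vehicle_arm <- names(doses)[doses == 0][1]
  if (is.na(vehicle_arm)) stop("config must include a vehicle (dose 0) arm")
  veh <- bundle$volumes[bundle$volumes$arm == vehicle_arm, ]
  dose_arms <- names(doses)[doses > 0]
  eff <- do.call(rbind, lapply(dose_arms, function(a) {
    d <- bundle$volumes[bundle$volumes$arm == a, ]
    r <- tgi(d, veh)
    data.frame(arm = a, dose_mgkg = doses[[a]],
               gm_pct_change = r$gm_pct_change_treated,
               gm_pct_change_vehicle = r$gm_pct_change_control,
               tgi_pct = r$tgi, p_vs_vehicle = r$p,
               significant = r$p < alpha, stringsAsFactors = FALSE)
  }))

  # cohort waterfall with planted sensitivity
  co <- cfg$cohort
  cohort <- simulate_cohort(co$n_models, co$sensitive_fraction, truth, noise)
  wf <- waterfall(cohort)
  planted_frac <- mean(cohort$planted_sensitive)
  observed_frac <- mean(wf$sensitivity == "sensitive")

  wt <- function(d, f) utils::write.table(
    d, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(eff, "tgi.tsv")
  wt(as.data.frame(wf), "waterfall.tsv")
  fit_tab <- data.frame(parameter = c("kout", "smax", "sc50"),
                        estimate = unname(coef(pkpd)),
                        true_value = c(truth$er$kout, truth$er$smax,
                                       truth$er$sc50))
  wt(fit_tab, "pkpd_fit.tsv")
  log_lines <- c(
    "serdpd pipeline run",
    paste0("package_version: ", as.character(utils::packageVersion("serdpd"))),
    paste0("seed: ", seed),
    paste0("alpha: ", alpha),
    paste0("config: ", basename(config_file)),
    paste0("arms: ", paste(sprintf("%s=%g", names(doses), doses), collapse = ", ")),
    paste0("n_per_arm: ", design$n_per_arm),
    paste0("duration_days: ", design$duration_days),
    paste0("cohort_sensitive_fraction_planted: ", planted_frac),
    paste0("cohort_sensitive_fraction_observed: ", observed_frac))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))

  invisible(list(bundle = bundle, pkpd_fit = pkpd, efficacy = eff,
                 waterfall = wf,
                 cohort_sensitive_fraction = c(planted = planted_frac,
                                               observed = observed_frac)))
}
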