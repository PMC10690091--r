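#' Noise model for synthetic studies
#'
#' Measurement error is multiplicative lognormal for tumor volumes and
#' plasma concentrations (caliper and bioanalytical error scale with the
#' measured value) and additive Gaussian on log-scale expression. A CV of c
#' maps to lognormal sdlog `sqrt(log(1 + c^2))` with median 1, so zero CV
#' reproduces the deterministic model exactly.
#'
#' @param volume_cv Coefficient of variation of tumor-volume measurements.
#' @param conc_cv CV of concentration measurements.
#' @param er_cv CV of relative-ER measurements.
#' @param expression_sd Additive SD on log expression.
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(volume_cv = 0.15, conc_cv = 0.10, er_cv = 0.15,
                        expression_sd = 1, seed = 1) {
  vals <- c(volume_cv, conc_cv, er_cv, expression_sd)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("all noise CV/SD values must be finite and >= 0")
  if (!is.numeric(seed) || length(seed) != 1 || seed != round(seed))
    stop("'seed' must be a single integer")
  structure(list(volume_cv = volume_cv, conc_cv = conc_cv, er_cv = er_cv,
                 expression_sd = expression_sd, seed = as.integer(seed)),
            class = "noise_model")
}

# deterministic substream seed: same (seed, index) -> same stream,
# independent of the order in which streams are consumed
substream_seed <- function(seed, index) {
  ((seed %% 2147483647) * 69069 + index * 1013904223) %% 2147483647
}

# lognormal multiplicative noise factors with median 1 and CV cv
ln_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  exp(stats::rnorm(n, 0, sqrt(log(1 + cv^2))))
}

#' Twice-weekly measurement schedule
#'
#' Caliper measurement days on a Monday/Thursday-style cadence:
#' 0, 3, 7, 10, 14, ... up to the study duration.
#'
#' @param duration_days Length of the study in days.
#' @return Integer vector of measurement days starting at 0.
#' @export
twice_weekly <- function(duration_days) {
  d <- cumsum(c(0, rep(c(3, 4), ceiling(duration_days / 7) + 1)))
  d[d <= duration_days]
}

#' Synthetic efficacy-study design
#'
#' @param arms Named list mapping arm labels to [dose_regimen()] objects;
#'   use `NULL` (or dose 0) for the vehicle arm.
#' @param n_per_arm Animals per arm (>= 1).
#' @param enrollment_volume_range Baseline tumor volume range (mm^3) from
#'   which animals are enrolled; default 150-300.
#' @param duration_days Study duration in days (> 0).
#' @param measurement_days Caliper days; default twice weekly from day 0.
#' @return An object of class `study_design`.
#' @examples
#' study_design(arms = list(vehicle = NULL, cami_10 = dose_regimen(10)),
#'              n_per_arm = 8, duration_days = 21)
#' @export
study_design <- function(arms, n_per_arm = 8,
                         enrollment_volume_range = c(150, 300),
                         duration_days = 21,
                         measurement_days = twice_weekly(duration_days)) {
  if (!is.list(arms) || length(arms) == 0 || is.null(names(arms)) ||
      any(names(arms) == ""))
    stop("'arms' must be a non-empty named list of dose regimens (NULL for vehicle)")
  for (a in names(arms)) {
    if (!is.null(arms[[a]]) && !inherits(arms[[a]], "dose_regimen"))
      stop("arm '", a, "' must be a dose_regimen or NULL")
  }
  if (!is.numeric(n_per_arm) || n_per_arm < 1 || n_per_arm != round(n_per_arm))
    stop("'n_per_arm' must be a positive integer")
  r <- enrollment_volume_range
  if (length(r) != 2 || any(!is.finite(r)) || r[1] <= 0 || r[1] >= r[2])
    stop("'enrollment_volume_range' must be (min, max) with 0 < min < max")
  if (!is.numeric(duration_days) || duration_days <= 0)
    stop("'duration_days' must be positive")
  md <- measurement_days
  if (length(md) < 2 || md[1] != 0 || any(diff(md) <= 0))
    stop("'measurement_days' must be strictly increasing and start at 0")
  if (max(md) > duration_days)
    stop("'measurement_days' must not exceed 'duration_days'")
  structure(list(arms = arms, n_per_arm = as.integer(n_per_arm),
                 enrollment_volume_range = r,
                 duration_days = duration_days, measurement_days = md),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  doses <- vapply(x$arms, function(r) if (is.null(r)) 0 else r$dose, 0)
  cat(sprintf("Study design: %d arms (%s), n = %d/arm, %g days, baseline %g-%g mm^3\n",
              length(x$arms),
              paste(sprintf("%s: %g mg/kg", names(x$arms), doses), collapse = ", "),
              x$n_per_arm, x$duration_days,
              x$enrollment_volume_range[1], x$enrollment_volume_range[2]))
  invisible(x)
}

#' Ground-truth parameter bundle for simulation
#'
#' Records the generating parameters of a synthetic study so downstream
#' fits can be checked against the truth.
#'
#' @param pk A [pk_params()] object.
#' @param er An [er_params()] object.
#' @param growth A [growth_params()] object.
#' @param signature_effect Optional per-gene z-shift applied to treated
#'   expression samples.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(pk, er, growth, signature_effect = NULL) {
  stopifnot(inherits(pk, "pk_params"), inherits(er, "er_params"),
            inherits(growth, "growth_params"))
  structure(list(pk = pk, er = er, growth = growth,
                 signature_effect = signature_effect),
            class = "ground_truth")
}

#' Default ground truth of the packaged demo study
#'
#' ER turnover is anchored at a basal half-life of 3 h, maximal 10-fold
#' degradation stimulation (`smax = 9`) and an in vivo free degradation
#' IC50 of 0.4 nmol/L. PK is a one-compartment oral profile (absorption
#' 1/h, elimination half-life 5 h, V/F 5 L/kg, free fraction 1%) whose
#' once-daily 1-30 mg/kg arms give free troughs bracketing the IC50.
#' Vehicle tumors grow at 0.02 log10 mm^3/day (doubling ~15 days) and full
#' ER loss reverses growth (`bkill = 0.05`).
#'
#' @return A [ground_truth()] object.
#' @export
default_truth <- function() {
  ground_truth(pk = pk_params(ka = 1, ke = log(2) / 5, vd_over_f = 5, fu = 0.01),
               er = er_params(kout = log(2) / 3, smax = 9, sc50 = 0.4),
               growth = growth_params(b0 = 0.02, bkill = 0.05, gamma = 1))
}

# extend a regimen so dosing covers the study duration
cover_duration <- function(regimen, duration_days) {
  if (is.null(regimen) || regimen$dose == 0) return(regimen)
  need <- ceiling(duration_days * 24 / regimen$interval)
  regimen$n_doses <- max(regimen$n_doses, need)
  regimen
}

#' Simulate a complete synthetic efficacy study
#'
#' For each arm, plasma exposure follows the ground-truth PK model, the ER
#' level follows the turnover ODE driven by the free concentration, and each
#' animal's tumor grows according to the ER-linked exponential model from a
#' baseline drawn uniformly from the enrollment range. Noise is applied per
#' the [noise_model()]; with all noise at zero every observable equals the
#' deterministic model exactly. Each animal, arm-level concentration series
#' and ER replicate has its own seeded substream, so the same seed
#' reproduces the identical bundle and per-arm subsets are reproducible.
#'
#' @param design A [study_design()].
#' @param truth A [ground_truth()].
#' @param noise A [noise_model()].
#' @param er_times_h Sampling times (hours from first dose) of the ER time
#'   courses.
#' @param conc_times_h Sampling times of the plasma concentration series.
#' @return An object of class `study_bundle`: list with data frames
#'   `volumes` (animal, arm, day, volume_mm3), `conc` (arm, time_h,
#'   conc_nM, free_nM), `er` (arm, replicate, time_h, rel_er), plus `truth`
#'   and `design` echoes.
#' @examples
#' des <- study_design(list(vehicle = NULL, cami_10 = dose_regimen(10)),
#'                     n_per_arm = 4, duration_days = 14)
#' b <- simulate_study(des, default_truth(), noise_model(seed = 7))
#' head(b$volumes)
#' @export
simulate_study <- function(design, truth, noise,
                           er_times_h = c(0, 0.5, 1, 2, 4, 8, 12, 24, 25, 28, 36, 48),
                           conc_times_h = c(0.25, 0.5, 1, 2, 4, 8, 12, 24)) {
  stopifnot(inherits(design, "study_design"), inherits(truth, "ground_truth"),
            inherits(noise, "noise_model"))
  vol_l <- list(); conc_l <- list(); er_l <- list()
  arm_names <- names(design$arms)
  fine_h <- sort(unique(c(seq(0, design$duration_days * 24, by = 2),
                          er_times_h)))
  for (ai in seq_along(arm_names)) {
    arm <- arm_names[ai]
    reg <- cover_duration(design$arms[[arm]], design$duration_days)
    vehicle <- is.null(reg) || reg$dose == 0

    # exposure and deterministic ER course for the arm
    if (vehicle) {
      cu_fn <- 0
      conc_det <- data.frame(time_h = conc_times_h,
                             conc_nM = 0, free_nM = 0)
    } else {
      cu_fn <- free_conc_fn(truth$pk, reg)
      conc_det <- predict_concentration(truth$pk, reg, conc_times_h)
    }
    er_fine <- simulate_er(truth$er, cu_fn, fine_h)

    # arm-level concentration series with bioanalytical noise
    set.seed(substream_seed(noise$seed, 500000 + ai))
    fac <- ln_noise(nrow(conc_det), noise$conc_cv)
    conc_l[[arm]] <- data.frame(arm = arm, time_h = conc_det$time_h,
                                conc_nM = conc_det$conc_nM * fac,
                                free_nM = conc_det$free_nM * fac,
                                stringsAsFactors = FALSE)

    # ER time-course replicates (one per animal)
    er_det <- er_fine$rel_er[match(er_times_h, er_fine$time_h)]
    for (r in seq_len(design$n_per_arm)) {
      set.seed(substream_seed(noise$seed, 600000 + ai * 1000 + r))
      er_l[[paste(arm, r)]] <- data.frame(
        arm = arm, replicate = r, time_h = er_times_h,
        rel_er = er_det * ln_noise(length(er_times_h), noise$er_cv),
        stringsAsFactors = FALSE)
    }

    # per-animal tumor trajectories
    for (an in seq_len(design$n_per_arm)) {
      set.seed(substream_seed(noise$seed, ai * 1000 + an))
      v0 <- stats::runif(1, design$enrollment_volume_range[1],
                         design$enrollment_volume_range[2])
      det <- simulate_tumor(truth$growth, er_fine, design$measurement_days,
                            v0, e0 = truth$er$e0)
      vol_l[[paste(arm, an)]] <- data.frame(
        animal = sprintf("%s_%02d", arm, an), arm = arm,
        day = det$day,
        volume_mm3 = det$volume_mm3 * ln_noise(nrow(det), noise$volume_cv),
        stringsAsFactors = FALSE)
    }
  }
  structure(list(volumes = do.call(rbind, c(vol_l, make.row.names = FALSE)),
                 conc = do.call(rbind, c(conc_l, make.row.names = FALSE)),
                 er = do.call(rbind, c(er_l, make.row.names = FALSE)),
                 truth = truth, design = design, noise = noise),
            class = "study_bundle")
}

#' @export
print.study_bundle <- function(x, ...) {
  cat("Synthetic study bundle\n")
  print(x$design)
  cat(sprintf("  %d volume rows, %d concentration rows, %d ER rows (seed %d)\n",
              nrow(x$volumes), nrow(x$conc), nrow(x$er), x$noise$seed))
  invisible(x)
}

#' Simulate an expression matrix with planted signature genes
#'
#' Non-signature genes are drawn from the same distribution in both groups;
#' in the treated group, induced signature genes are shifted up and
#' repressed genes down by `shift` standard deviations of the expression
#' noise (a shift in z units of the generating noise).
#'
#' @param n_genes Total number of genes (must be >= the signature size, > 0).
#' @param n_samples_per_group Samples per group (control and treated).
#' @param signature A [gene_signature()]; its genes are included in the
#'   matrix by construction.
#' @param shift Planted shift in z units (finite; may be 0 or negative).
#' @param noise A [noise_model()]; uses `expression_sd` and `seed`.
#' @return A list with `matrix` (genes x samples, log scale), `group`
#'   (factor control/treated per sample) and `shift` echo.
#' @export
simulate_expression <- function(n_genes, n_samples_per_group, signature,
                                shift, noise) {
  stopifnot(inherits(signature, "gene_signature"), inherits(noise, "noise_model"))
  if (!is.numeric(n_genes) || n_genes < 1)
    stop("'n_genes' must be a positive count")
  if (n_genes < nrow(signature))
    stop("'n_genes' is smaller than the signature (", nrow(signature), " genes)")
  if (!is.numeric(n_samples_per_group) || n_samples_per_group < 2)
    stop("'n_samples_per_group' must be at least 2")
  if (!is.finite(shift)) stop("'shift' must be finite")
  n_fill <- n_genes - nrow(signature)
  genes <- c(signature$gene,
             if (n_fill > 0) sprintf("filler%05d", seq_len(n_fill)))
  n <- as.integer(n_samples_per_group)
  set.seed(substream_seed(noise$seed, 700001))
  mu <- stats::rnorm(n_genes, 7, 1)                     # gene-level baselines
  mat <- matrix(stats::rnorm(n_genes * 2 * n, 0, noise$expression_sd),
                nrow = n_genes) + mu
  rownames(mat) <- genes
  colnames(mat) <- c(sprintf("control_%02d", seq_len(n)),
                     sprintf("treated_%02d", seq_len(n)))
  group <- factor(rep(c("control", "treated"), each = n),
                  levels = c("control", "treated"))
  idx <- match(signature$gene, genes)
  mat[idx, group == "treated"] <- mat[idx, group == "treated"] +
    signature$direction * shift * noise$expression_sd
  list(matrix = mat, group = group, shift = shift)
}

#' Simulate a first-order protein decay time course
#'
#' Noiseless levels follow `exp(-log(2) * t / half_life)` exactly;
#' measurement noise is multiplicative lognormal with CV `er_cv`.
#'
#' @param half_life Half-life in hours (> 0).
#' @param times Non-negative sampling times (hours).
#' @param noise A [noise_model()] (uses `er_cv` and `seed`).
#' @return An `er_time_course` data frame (`time_h`, `rel_er`).
#' @export
simulate_decay_course <- function(half_life, times, noise) {
  stopifnot(inherits(noise, "noise_model"))
  if (!is.numeric(half_life) || length(half_life) != 1 || half_life <= 0)
    stop("'half_life' must be a single positive number of hours")
  if (any(times < 0)) stop("'times' must be non-negative")
  set.seed(substream_seed(noise$seed, 800001))
  lev <- exp(-log(2) * times / half_life) * ln_noise(length(times), noise$er_cv)
  out <- data.frame(time_h = times, rel_er = lev)
  class(out) <- c("er_time_course", "data.frame")
  out
}

#' Simulate a PDX cohort with planted sensitivity
#'
#' Generates per-model treated and vehicle arms: in planted-sensitive
#' models the drug drives regression (full `bkill`), in insensitive models
#' the ER-growth link is absent (`bkill = 0`). Percent tumor-volume changes
#' are summarized per model as the geometric-mean change of the treated
#' arm, the quantity plotted on cohort waterfalls.
#'
#' @param n_models Number of PDX-like models in the cohort.
#' @param sensitive_fraction Fraction of models planted as drug-sensitive;
#'   the planted count is `round(n_models * sensitive_fraction)`.
#' @param truth A [ground_truth()]; `growth$bkill` is used for sensitive
#'   models and 0 for insensitive ones.
#' @param noise A [noise_model()].
#' @param regimen Treated-arm regimen (default 10 mg/kg QD).
#' @param n_per_arm Animals per arm per model.
#' @param duration_days Study length per model.
#' @return A data frame with one row per model: `model`, `pct_change`
#'   (geometric-mean %TV change of the treated arm), `pct_change_vehicle`,
#'   `p` (one-tailed Welch vs vehicle) and `planted_sensitive`.
#' @export
simulate_cohort <- function(n_models, sensitive_fraction, truth, noise,
                            regimen = dose_regimen(10, 24, 1),
                            n_per_arm = 5, duration_days = 21) {
  if (n_models < 1) stop("'n_models' must be >= 1")
  if (sensitive_fraction < 0 || sensitive_fraction > 1)
    stop("'sensitive_fraction' must be in [0, 1]")
  n_sens <- round(n_models * sensitive_fraction)
  planted <- rep(c(TRUE, FALSE), c(n_sens, n_models - n_sens))
  rows <- vector("list", n_models)
  for (m in seq_len(n_models)) {
    g <- truth$growth
    if (!planted[m]) g <- growth_params(g$b0, 0, g$gamma)
    tr_m <- ground_truth(truth$pk, truth$er, g)
    des <- study_design(list(vehicle = NULL, treated = regimen),
                        n_per_arm = n_per_arm, duration_days = duration_days)
    nm <- noise
    nm$seed <- as.integer(substream_seed(noise$seed, 900000 + m))
    b <- simulate_study(des, tr_m, nm,
                        er_times_h = c(0, 24), conc_times_h = c(1, 24))
    tr <- b$volumes[b$volumes$arm == "treated", ]
    ve <- b$volumes[b$volumes$arm == "vehicle", ]
    res <- tgi(tr, ve)
    rows[[m]] <- data.frame(
      model = sprintf("model_%02d", m),
      pct_change = res$gm_pct_change_treated,
      pct_change_vehicle = res$gm_pct_change_control,
      p = res$p, planted_sensitive = planted[m],
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Write a study bundle as delimited text
#'
#' Writes `volumes.tsv`, `conc.tsv`, `er.tsv` plus `truth.yaml` and
#' `design.yaml` echoes into a directory.
#'
#' @param bundle A `study_bundle` from [simulate_study()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_study_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "study_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(d, f) utils::write.table(
    d, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(bundle$volumes, "volumes.tsv")
  wt(bundle$conc, "conc.tsv")
  wt(bundle$er, "er.tsv")
  tr <- bundle$truth
  yaml::write_yaml(list(
    pk = unclass(tr$pk), er = unclass(tr$er), growth = unclass(tr$growth)),
    file.path(dir, "truth.yaml"))
  des <- bundle$design
  yaml::write_yaml(list(
    arms = lapply(des$arms, function(r) if (is.null(r)) list(dose = 0)
                  else unclass(r)),
    n_per_arm = des$n_per_arm,
    enrollment_volume_range = des$enrollment_volume_range,
    duration_days = des$duration_days,
    measurement_days = des$measurement_days,
    seed = bundle$noise$seed),
    file.path(dir, "design.yaml"))
  invisible(dir)
}

#' Read the tables of a written study bundle
#'
#' @param dir Directory written by [write_study_bundle()].
#' @return A list with `volumes`, `conc`, `er` data frames and `truth`,
#'   `design` lists.
#' @export
read_study_bundle <- function(dir) {
  rd <- function(f) utils::read.delim(file.path(dir, f), stringsAsFactors = FALSE)
  list(volumes = rd("volumes.tsv"), conc = rd("conc.tsv"), er = rd("er.tsv"),
       truth = yaml::read_yaml(file.path(dir, "truth.yaml")),
       design = yaml::read_yaml(file.path(dir, "design.yaml")))
}
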