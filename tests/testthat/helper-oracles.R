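# Independently coded oracles, kept deliberately separate from the package
# implementation paths they check.

# Welch unequal-variance t statistic, Satterthwaite df and one-tailed
# (less) p, written straight from the textbook formulas.
welch_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- stats::var(x) / nx
  vy <- stats::var(y) / ny
  tstat <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (nx - 1) + vy^2 / (ny - 1))
  list(t = tstat, df = df, p_less = stats::pt(tstat, df))
}

# simple linear regression by explicit normal equations, with the
# 95% confidence interval of the slope
ols_oracle <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  b <- sum((x - mean(x)) * (y - mean(y))) / sxx
  a <- mean(y) - b * mean(x)
  rss <- sum((y - a - b * x)^2)
  se_b <- sqrt(rss / (n - 2) / sxx)
  tq <- stats::qt(0.975, n - 2)
  list(a = a, b = b, ci_b = c(b - tq * se_b, b + tq * se_b))
}

# one-way ANCOVA F test for the group term by explicit projections
ancova_oracle <- function(score, group, covariate = NULL) {
  g <- factor(group)
  dummies <- outer(as.character(g), levels(g)[-1], "==") * 1
  if (is.null(covariate)) {
    Xn <- matrix(1, length(score), 1)
    Xf <- cbind(1, dummies)
  } else {
    Xn <- cbind(1, covariate)
    Xf <- cbind(1, covariate, dummies)
  }
  rss <- function(X) {
    beta <- solve(t(X) %*% X, t(X) %*% score)
    sum((score - X %*% beta)^2)
  }
  r_null <- rss(Xn); r_full <- rss(Xf)
  df1 <- nlevels(g) - 1
  df2 <- length(score) - ncol(Xf)
  Fstat <- ((r_null - r_full) / df1) / (r_full / df2)
  list(F = Fstat, p = stats::pf(Fstat, df1, df2, lower.tail = FALSE))
}

# closed-form steady state of the ER turnover model under constant exposure
er_ss_oracle <- function(e0, smax, cu_over_sc50) {
  e0 / (1 + smax * cu_over_sc50 / (1 + cu_over_sc50))
}

# standard 4-arm QD design used by several recovery tests
four_dose_design <- function(n_per_arm = 8, duration_days = 21) {
  study_design(list(vehicle = NULL,
                    d1 = dose_regimen(1), d3 = dose_regimen(3),
                    d10 = dose_regimen(10), d30 = dose_regimen(30)),
               n_per_arm = n_per_arm, duration_days = duration_days)
}

arm_regimens <- function(design) {
  lapply(design$arms, serdpd:::cover_duration,
         duration_days = design$duration_days)
}

# two-timepoint volume table builder for efficacy statistics tests
volume_table <- function(arm, ratios, v0 = 200, end_day = 21) {
  do.call(rbind, lapply(seq_along(ratios), function(i) {
    data.frame(animal = sprintf("%s_%02d", arm, i), arm = arm,
               day = c(0, end_day),
               volume_mm3 = c(v0, v0 * ratios[i]),
               stringsAsFactors = FALSE)
  }))
}
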