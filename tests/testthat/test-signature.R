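demo_sig <- function() {
  read_signature(system.file("extdata", "er_activity_signature_synthetic.tsv",
                             package = "serdpd"))
}

test_that("z-scored rows have mean 0 and unit SD under both conventions", {
  set.seed(1)
  m <- matrix(rnorm(50 * 8, 5, 2), 50, 8,
              dimnames = list(sprintf("g%02d", 1:50), sprintf("s%d", 1:8)))
  zp <- zscore_normalize(m, "population")
  expect_true(all(abs(rowMeans(zp)) < 1e-12))
  expect_true(all(abs(sqrt(rowSums(zp^2) / 8) - 1) < 1e-12))
  zs <- zscore_normalize(m, "sample")
  expect_true(all(abs(apply(zs, 1, sd) - 1) < 1e-12))
  # two samples {1, 3}: deviations are +/-1, so dividing by the population
  # SD (over n = 2, SD = 1) gives +/-1 and by the sample SD (over n - 1,
  # SD = sqrt(2)) gives +/-0.707
  m2 <- matrix(c(1, 3), 1, 2, dimnames = list("g", c("a", "b")))
  expect_equal(as.numeric(zscore_normalize(m2, "population")),
               c(-1, 1), tolerance = 1e-12)
  expect_equal(as.numeric(zscore_normalize(m2, "sample")),
               c(-1, 1) / sqrt(2), tolerance = 1e-12)
})

test_that("constant genes are dropped with a warning", {
  m <- rbind(g1 = c(1, 2, 3), g2 = c(5, 5, 5))
  expect_warning(z <- zscore_normalize(m), "constant gene")
  expect_equal(rownames(z), "g1")
  expect_error(zscore_normalize(m[, 1, drop = FALSE]), "2 samples")
})

test_that("signature scores respect zero, antisymmetry and cancellation", {
  sig <- gene_signature(c("a", "b", "c"), c(1, 1, -1))
  z <- matrix(0, 3, 4, dimnames = list(c("a", "b", "c"), sprintf("s%d", 1:4)))
  expect_true(all(score_signature(z, sig) == 0))

  set.seed(2)
  z[] <- rnorm(12)
  s1 <- score_signature(z, sig)
  flipped <- gene_signature(sig$gene, -sig$direction)
  expect_equal(score_signature(z, flipped), -s1, tolerance = 1e-12)

  # a gene and its mirror with identical values cancel
  z2 <- rbind(z, d = z["a", ], e = z["a", ])
  sig2 <- gene_signature(c(sig$gene, "d", "e"), c(sig$direction, 1, -1))
  expect_equal(score_signature(z2, sig2),
               s1 * 3 / 5, tolerance = 1e-12)  # mean over 5 genes, extra pair sums to 0

  # a global shift on one sample moves its score by mean(direction) * shift
  z3 <- z
  z3[, 2] <- z3[, 2] + 1.7
  s3 <- score_signature(z3, sig)
  expect_equal(unname(s3[2] - s1[2]), mean(sig$direction) * 1.7,
               tolerance = 1e-12)
  expect_equal(s3[-2], s1[-2], tolerance = 1e-12)
})

test_that("missing signature genes are reported and bounded", {
  sig <- gene_signature(c("a", "b", "x", "y"), c(1, 1, -1, -1))
  z <- matrix(rnorm(8), 2, 4, dimnames = list(c("a", "b"), sprintf("s%d", 1:4)))
  expect_error(score_signature(z, sig, min_present = 0.75), "missing")
  expect_message(s <- score_signature(z, sig, min_present = 0.5), "absent")
  expect_true(all(is.finite(s)))
  znone <- matrix(rnorm(4), 1, 4, dimnames = list("q", sprintf("s%d", 1:4)))
  expect_error(score_signature(znone, sig), "no signature genes")
})

test_that("simulated expression plants the signature shift it advertises", {
  sig <- demo_sig()
  noise <- noise_model(expression_sd = 1, seed = 7)
  # null case: no planted shift
  sim0 <- simulate_expression(400, 20, sig, shift = 0, noise = noise)
  sc0 <- score_signature(zscore_normalize(sim0$matrix), sig)
  d0 <- mean(sc0[sim0$group == "treated"]) - mean(sc0[sim0$group == "control"])
  se0 <- sqrt(var(sc0[sim0$group == "treated"]) / 20 +
                var(sc0[sim0$group == "control"]) / 20)
  expect_lt(abs(d0), 3 * se0)

  # planted 2-z shift: z-scoring pools both groups, so the expected score
  # delta is shift / sqrt((2n-1)/(2n) + shift^2/4)
  sim2 <- simulate_expression(400, 20, sig, shift = 2, noise = noise)
  sc2 <- score_signature(zscore_normalize(sim2$matrix), sig)
  d2 <- mean(sc2[sim2$group == "treated"]) - mean(sc2[sim2$group == "control"])
  se2 <- sqrt(var(sc2[sim2$group == "treated"]) / 20 +
                var(sc2[sim2$group == "control"]) / 20)
  expected <- 2 / sqrt(39 / 40 + 1)
  expect_lt(abs(d2 - expected), 3 * se2)

  # non-signature genes are distributed identically across groups
  filler <- grepl("^filler", rownames(sim2$matrix))
  fd <- rowMeans(sim2$matrix[filler, sim2$group == "treated"]) -
    rowMeans(sim2$matrix[filler, sim2$group == "control"])
  expect_lt(abs(mean(fd)), 3 * sd(fd) / sqrt(sum(filler)))

  expect_error(simulate_expression(0, 10, sig, 1, noise), "positive count")
  expect_error(simulate_expression(5, 10, sig, 1, noise), "smaller than the signature")
})

test_that("scores are invariant to gene-wise affine transforms of the raw matrix", {
  sig <- gene_signature(c("a", "b", "c"), c(1, -1, 1))
  set.seed(9)
  m <- matrix(rnorm(3 * 6), 3, 6, dimnames = list(c("a", "b", "c"), sprintf("s%d", 1:6)))
  s1 <- score_signature(zscore_normalize(m), sig)
  m2 <- m * c(2, 0.5, 10) + c(-1, 4, 100)  # per-gene scale and offset
  s2 <- score_signature(zscore_normalize(m2), sig)
  expect_equal(s1, s2, tolerance = 1e-12)
})

test_that("ANCOVA matches the normal-equations oracle and its degenerate limits", {
  set.seed(4)
  n <- 12
  group <- rep(c("ctl", "trt"), each = n)
  covariate <- rnorm(2 * n, 200, 30)
  score <- 0.3 * (group == "trt") + 0.01 * covariate + rnorm(2 * n)
  res <- compare_scores_ancova(score, group, covariate)
  oracle <- ancova_oracle(score, group, covariate)
  expect_equal(res$p, oracle$p, tolerance = 1e-9)
  expect_equal(res$F, oracle$F, tolerance = 1e-9)
  expect_true(res$covariate_used)

  # zero-variance covariate reduces to one-way ANOVA
  res0 <- compare_scores_ancova(score, group, rep(5, 2 * n))
  anova_o <- ancova_oracle(score, group, NULL)
  expect_equal(res0$p, anova_o$p, tolerance = 1e-9)
  expect_false(res0$covariate_used)

  # a planted 2-sd group shift is detected
  shifted <- rnorm(20) + rep(c(0, 2), each = 10)
  resp <- compare_scores_ancova(shifted, rep(c("a", "b"), each = 10),
                                rnorm(20))
  expect_lt(resp$p, 0.01)

  expect_error(compare_scores_ancova(score, rep("one", 2 * n), covariate),
               "2 groups")
  expect_error(compare_scores_ancova(score[1:3], c("a", "a", "b"), NULL),
               "at least 2 samples")
})
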