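#' Direction-annotated gene signature
#'
#' A gene set with a direction per gene: +1 for genes induced by the
#' pathway's activity (e.g. estradiol-induced ER targets), -1 for repressed
#' genes.
#'
#' @param gene Character vector of gene identifiers (unique, non-empty).
#' @param direction Integer vector of +1/-1 matching `gene`.
#' @return An object of class `gene_signature` (data frame with columns
#'   `gene`, `direction`).
#' @examples
#' gene_signature(c("GREB1", "PGR", "CXCL12"), c(1, 1, -1))
#' @export
gene_signature <- function(gene, direction) {
  gene <- as.character(gene)
  if (length(gene) == 0) stop("signature must contain at least one gene")
  if (anyDuplicated(gene)) stop("duplicate gene ids in signature")
  if (length(direction) != length(gene))
    stop("'gene' and 'direction' must have the same length")
  if (!all(direction %in% c(-1, 1)))
    stop("'direction' entries must be +1 (induced) or -1 (repressed)")
  structure(data.frame(gene = gene, direction = as.integer(direction),
                       stringsAsFactors = FALSE),
            class = c("gene_signature", "data.frame"))
}

#' Read a gene signature from a two-column text file
#'
#' @param path Tab-delimited file with columns `gene` and `direction`
#'   (+1/-1), with header.
#' @return A [gene_signature()].
#' @export
read_signature <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "direction") %in% names(d)))
    stop("signature file needs columns 'gene' and 'direction'")
  gene_signature(d$gene, d$direction)
}

#' Z-score an expression matrix gene-wise
#'
#' Standardizes each gene (row) across samples: `(x - mean) / SD`. Genes
#' with zero variance carry no information on the z scale and are dropped
#' with a warning.
#'
#' @param mat Numeric matrix, genes in rows (unique rownames), samples in
#'   columns; at least 2 samples.
#' @param sd_type `"population"` (divide by n; default) or `"sample"`
#'   (divide by n-1).
#' @return The z-scored matrix (possibly with fewer rows).
#' @export
zscore_normalize <- function(mat, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (!is.matrix(mat) || !is.numeric(mat)) stop("'mat' must be a numeric matrix")
  if (is.null(rownames(mat))) stop("'mat' must have gene ids as rownames")
  if (anyDuplicated(rownames(mat))) stop("duplicate gene ids in matrix")
  n <- ncol(mat)
  if (n < 2) stop("at least 2 samples are required")
  mu <- rowMeans(mat)
  cent <- mat - mu
  ss <- rowSums(cent^2)
  sd <- sqrt(ss / if (sd_type == "population") n else (n - 1))
  const <- sd == 0 | !is.finite(sd)
  if (any(const)) {
    warning(sum(const), " constant gene(s) dropped from z-scoring: ",
            paste(utils::head(rownames(mat)[const], 5), collapse = ", "),
            if (sum(const) > 5) ", ..." else "")
    cent <- cent[!const, , drop = FALSE]
    sd <- sd[!const]
  }
  cent / sd
}

#' Signature score per sample
#'
#' The score of a sample is the mean over signature genes of
#' `direction * z`, so activation of the pathway (induced genes up,
#' repressed genes down) raises the score.
#'
#' @param zmat Z-scored matrix from [zscore_normalize()].
#' @param signature A [gene_signature()].
#' @param min_present Minimum fraction of signature genes that must be
#'   present in the matrix (default 0.5); missing genes are reported.
#' @return Named numeric vector of per-sample scores.
#' @export
score_signature <- function(zmat, signature, min_present = 0.5) {
  stopifnot(inherits(signature, "gene_signature"))
  present <- signature$gene %in% rownames(zmat)
  if (!any(present)) stop("no signature genes present in the matrix")
  if (mean(present) < min_present)
    stop(sprintf("only %.0f%% of signature genes present (< %.0f%% required); missing: %s",
                 100 * mean(present), 100 * min_present,
                 paste(utils::head(signature$gene[!present], 10), collapse = ", ")))
  if (any(!present))
    message("signature genes absent from matrix: ",
            paste(signature$gene[!present], collapse = ", "))
  sig <- signature[present, , drop = FALSE]
  sub <- zmat[sig$gene, , drop = FALSE]
  colMeans(sub * sig$direction)
}

#' Compare signature scores between groups by one-way ANCOVA
#'
#' Fits `score ~ covariate + group` and reports the F test for the group
#' term adjusted for the covariate. A missing or zero-variance covariate
#' reduces the analysis to one-way ANOVA.
#'
#' @param score Numeric vector of per-sample scores.
#' @param group Factor or character of group labels (>= 2 groups, each with
#'   >= 2 samples).
#' @param covariate Optional numeric covariate (e.g. baseline tumor
#'   volume).
#' @return A list with `p` (F-test p for the group term), `F`, `df`, the
#'   fitted `lm`, and `covariate_used`.
#' @export
compare_scores_ancova <- function(score, group, covariate = NULL) {
  group <- factor(group)
  if (nlevels(group) < 2) stop("at least 2 groups are required")
  if (any(table(group) < 2)) stop("each group needs at least 2 samples")
  if (length(score) != length(group)) stop("'score' and 'group' lengths differ")
  use_cov <- !is.null(covariate)
  if (use_cov) {
    if (!is.numeric(covariate) || length(covariate) != length(score))
      stop("'covariate' must be numeric and match 'score' in length")
    if (stats::var(covariate) == 0) use_cov <- FALSE
  }
  if (use_cov) {
    full <- stats::lm(score ~ covariate + group)
    null <- stats::lm(score ~ covariate)
  } else {
    full <- stats::lm(score ~ group)
    null <- stats::lm(score ~ 1)
  }
  an <- stats::anova(null, full)
  list(p = an[2, "Pr(>F)"], F = an[2, "F"],
       df = c(an[2, "Df"], an[2, "Res.Df"]),
       model = full, covariate_used = use_cov)
}
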