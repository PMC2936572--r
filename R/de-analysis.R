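# Row-wise sample variance (denominator n - 1).
row_vars <- function(x) {
  n <- ncol(x)
  rowSums((x - rowMeans(x))^2) / (n - 1)
}

# Vectorized equal-variance two-sample t-test across rows. Degenerate
# convention: zero pooled variance gives p = 1 for equal means and p = 0
# otherwise.
student_p_rows <- function(ctrl, expe) {
  n1 <- ncol(ctrl); n2 <- ncol(expe)
  m1 <- rowMeans(ctrl); m2 <- rowMeans(expe)
  sp2 <- ((n1 - 1) * row_vars(ctrl) + (n2 - 1) * row_vars(expe)) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  p <- 2 * stats::pt(-abs((m2 - m1) / se), df = n1 + n2 - 2)
  degenerate <- se == 0
  p[degenerate] <- ifelse(m1[degenerate] == m2[degenerate], 1, 0)
  p
}

# Vectorized associative t-test: each row's residuals (deviations from the
# control mean profile) against the pooled reference residuals.
assoc_p_rows <- function(resid_mat, pool) {
  n <- ncol(resid_mat)
  N <- length(pool)
  m <- rowMeans(resid_mat)
  v <- row_vars(resid_mat)
  mp <- mean(pool)
  vp <- stats::var(pool)
  sp2 <- ((n - 1) * v + (N - 1) * vp) / (n + N - 2)
  t_stat <- (m - mp) / sqrt(sp2 * (1 / n + 1 / N))
  2 * stats::pt(-abs(t_stat), df = n + N - 2)
}

# Fold between two group means on the background-SD scale, as
# max(means) / min(means) with both terms floored at 1 SD unit: ratios with
# a denominator below one background SD are noise, not fold changes.
fold_from_means <- function(m1, m2) {
  hi <- pmax(m1, m2)
  lo <- pmin(m1, m2)
  pmax(hi, 1) / pmax(lo, 1)
}

#' Select the low-variability reference group
#'
#' Builds the internal standard of equal expression: among expressed genes
#' of the control subgroup, each gene's variance of residuals (deviations
#' from its own control mean) is compared by F-ratio against an estimate of
#' the purely technological variance, and genes below the critical value at
#' `alpha_F` are admitted. The technological variance is anchored robustly
#' on the lowest-variance quartile: its median variance divided by the
#' corresponding quantile of the scaled chi-square null distribution, so
#' that under an all-equal-variance null about `1 - alpha_F` of genes are
#' admitted. The admitted genes' residuals are pooled into the reference
#' residual distribution used by the associative test.
#'
#' @param control normalized control [expr_matrix()] (background-SD units).
#' @param expressed logical mask of expressed genes.
#' @param alpha_F significance level of the per-gene F criterion (default 0.05).
#' @param floor minimal admissible reference size (default 100).
#' @return a list of class `reference_group`: `gene_ids`, `pooled_residuals`,
#'   `resid_sd`, `tech_var`, `n_samples`.
#' @export
select_reference_group <- function(control, expressed, alpha_F = 0.05,
                                   floor = 100L) {
  validate_expr_matrix(control)
  n <- ncol(control)
  if (n < 2L) stop("need at least 2 control samples", call. = FALSE)
  if (sum(expressed) < floor) {
    stop("only ", sum(expressed), " expressed genes; reference floor is ",
         floor, call. = FALSE)
  }
  vals <- unclass(control)[expressed, , drop = FALSE]
  vars <- row_vars(vals)
  low_q <- vars[vars <= stats::quantile(vars, 0.25)]
  # median of the lowest-variance quartile sits at the 12.5th percentile of
  # the null chi2_(n-1)/(n-1) spread; dividing by that quantile de-biases it
  tech_var <- stats::median(low_q) / (stats::qchisq(0.125, n - 1) / (n - 1))
  crit <- stats::qf(1 - alpha_F, n - 1, Inf)
  admit <- vars / tech_var < crit
  if (sum(admit) < floor) {
    stop("reference group has ", sum(admit), " members (< ", floor,
         "); consider a larger alpha_F", call. = FALSE)
  }
  member <- vals[admit, , drop = FALSE]
  resid <- member - rowMeans(member)
  pooled <- as.vector(resid)
  structure(list(gene_ids = rownames(vals)[admit],
                 pooled_residuals = pooled,
                 resid_sd = sqrt(sum(resid^2) / (nrow(member) * (n - 1))),
                 tech_var = tech_var,
                 n_samples = n,
                 alpha_F = alpha_F),
            class = "reference_group")
}

#' @export
print.reference_group <- function(x, ...) {
  cat(sprintf("<reference_group> %d genes, %d pooled residuals, resid SD %.4g\n",
              length(x$gene_ids), length(x$pooled_residuals), x$resid_sd))
  invisible(x)
}

#' Student filter for one gene
#'
#' Classical equal-variance two-sample t-test of the control replicates
#' against the experimental replicates; the commonly accepted p < 0.05 gate
#' that keeps per-gene sensitivity while leaving false-positive control to
#' the associative test. Zero pooled variance yields p = 1 for equal means
#' and p = 0 otherwise.
#'
#' @param control_row,experimental_row numeric replicate vectors (>= 2 each).
#' @param alpha_student significance level (default 0.05).
#' @return list with `p_value` and logical `pass`.
#' @export
student_filter <- function(control_row, experimental_row,
                           alpha_student = 0.05) {
  if (length(control_row) < 2L || length(experimental_row) < 2L) {
    stop("student_filter needs at least 2 replicates per group", call. = FALSE)
  }
  p <- student_p_rows(matrix(control_row, nrow = 1L),
                      matrix(experimental_row, nrow = 1L))
  list(p_value = p, pass = p < alpha_student)
}

#' Associative t-test for one gene
#'
#' Tests whether a gene's replicated residuals (deviations of its
#' experimental replicates from the control mean profile) associate with
#' the pooled residual distribution of the reference group, by a two-sample
#' equal-variance t-test of the n experimental residuals against the
#' N-member reference pool (standard pooled-variance formula for unequal
#' sample sizes, df = n + N - 2).
#'
#' @param residuals numeric vector of the gene's experimental residuals
#'   (length >= 2).
#' @param reference a [select_reference_group()] result.
#' @return the two-sided p-value.
#' @export
associative_test <- function(residuals, reference) {
  stopifnot(inherits(reference, "reference_group"))
  if (length(residuals) < 2L) {
    stop("associative_test needs at least 2 residuals", call. = FALSE)
  }
  as.numeric(assoc_p_rows(matrix(residuals, nrow = 1L),
                          reference$pooled_residuals))
}

#' Apply the selection restrictions
#'
#' Final gene selection: a gene is selected iff its Student p-value is below
#' `alpha_student`, its associative p-value is below the Bonferroni-corrected
#' threshold `alpha_assoc / n_genes_tested`, its fold is at least `Fa`, and
#' the larger of its two group means is at least `Em`. Every failed
#' criterion is recorded in `reasons_rejected`.
#'
#' @param result a DE result `data.frame` with columns `mean_control`,
#'   `mean_experimental`, `fold`, `p_student`, `p_assoc` (one or many rows).
#' @param restrictions an [analysis_restrictions()].
#' @param n_genes_tested number of genes in the tested family (Bonferroni
#'   denominator).
#' @return `result` with columns `selected`, `direction`, `reasons_rejected`
#'   filled in.
#' @export
apply_restrictions <- function(result, restrictions, n_genes_tested) {
  stopifnot(inherits(restrictions, "analysis_restrictions"),
            n_genes_tested >= 1)
  thr_assoc <- restrictions$alpha_assoc / n_genes_tested
  pass <- cbind(student    = result$p_student < restrictions$alpha_student,
                assoc      = result$p_assoc < thr_assoc,
                fold       = result$fold >= restrictions$Fa,
                expression = pmax(result$mean_control,
                                  result$mean_experimental) >= restrictions$Em)
  pass[is.na(pass)] <- FALSE
  result$selected <- rowSums(pass) == ncol(pass)
  result$direction <- ifelse(result$selected,
                             ifelse(result$mean_experimental > result$mean_control,
                                    "up", "down"),
                             "none")
  result$reasons_rejected <- apply(pass, 1L, function(row) {
    paste(colnames(pass)[!row], collapse = ",")
  })
  result
}

#' Associative differential-expression analysis
#'
#' The full pipeline on normalized (background-SD unit) matrices: flag
#' expressed genes, build the low-variability reference group on the
#' control subgroup, compute per-gene group means, fold and Student
#' p-values, test each gene's experimental residuals against the reference
#' pool with the associative t-test, and apply the fold / expression /
#' significance restrictions with a Bonferroni-corrected associative
#' threshold.
#'
#' @param control,experimental aligned normalized [expr_matrix()] objects.
#' @param restrictions an [analysis_restrictions()].
#' @param expressed_threshold expression threshold in background-SD units
#'   (default 3) used for the reference-group candidate set.
#' @param alpha_F F-criterion level for the reference group (default 0.05).
#' @param reference_floor minimal reference-group size (default 100).
#' @param exclude logical mask of genes to exclude from testing entirely
#'   (e.g. from [exclude_hypervariable()]); excluded genes are never
#'   selected, carry reason `"excluded"`, and shrink the Bonferroni family.
#' @return a `data.frame` of class `de_result` with one row per gene:
#'   `gene_id`, `mean_control`, `mean_experimental`, `fold`, `p_student`,
#'   `p_assoc`, `selected`, `direction`, `reasons_rejected`. The reference
#'   group is attached as attribute `reference`.
#' @export
associative_analysis <- function(control, experimental,
                                 restrictions = analysis_restrictions(),
                                 expressed_threshold = 3,
                                 alpha_F = 0.05, reference_floor = 100L,
                                 exclude = NULL) {
  validate_expr_matrix(control)
  validate_expr_matrix(experimental)
  check_gene_alignment(rownames(control), rownames(experimental),
                       "control and experimental matrices")
  if (ncol(experimental) < 2L || ncol(control) < 2L) {
    stop("need at least 2 replicates per subgroup", call. = FALSE)
  }
  G <- nrow(control)
  if (is.null(exclude)) exclude <- rep(FALSE, G)

  combined_mean <- rowMeans(cbind(unclass(control), unclass(experimental)))
  expressed <- combined_mean > expressed_threshold & !exclude
  reference <- select_reference_group(control, expressed, alpha_F = alpha_F,
                                      floor = reference_floor)

  m_c <- rowMeans(control)
  m_e <- rowMeans(experimental)
  resid <- unclass(experimental) - m_c
  result <- data.frame(
    gene_id = rownames(control),
    mean_control = m_c,
    mean_experimental = m_e,
    fold = fold_from_means(m_c, m_e),
    p_student = student_p_rows(unclass(control), unclass(experimental)),
    p_assoc = assoc_p_rows(resid, reference$pooled_residuals),
    row.names = NULL, stringsAsFactors = FALSE
  )
  result <- apply_restrictions(result, restrictions,
                               n_genes_tested = sum(!exclude))
  if (any(exclude)) {
    result$selected[exclude] <- FALSE
    result$direction[exclude] <- "none"
    result$reasons_rejected[exclude] <- "excluded"
  }
  attr(result, "reference") <- reference
  class(result) <- c("de_result", class(result))
  result
}

#' Flag hypervariable genes
#'
#' Flags genes whose pooled within-group variance exceeds the technological
#' variance (anchored as in [select_reference_group()], on the pooled
#' within-group variances of expressed genes) by more than the F critical
#' value at `alpha_F`. The resulting mask can be passed to
#' [associative_analysis()] (argument `exclude`) and to the evaluation
#' drivers to drop these genes from both selection and denominator.
#'
#' @param control,experimental aligned normalized [expr_matrix()] objects.
#' @param alpha_F upper-tail significance level of the F criterion
#'   (default 0.01).
#' @param expressed_threshold expression threshold for the anchor set.
#' @return logical vector, `TRUE` for flagged genes.
#' @export
exclude_hypervariable <- function(control, experimental, alpha_F = 0.01,
                                  expressed_threshold = 3) {
  validate_expr_matrix(control)
  validate_expr_matrix(experimental)
  check_gene_alignment(rownames(control), rownames(experimental),
                       "control and experimental matrices")
  n1 <- ncol(control); n2 <- ncol(experimental)
  df <- n1 + n2 - 2
  vw <- ((n1 - 1) * row_vars(unclass(control)) +
         (n2 - 1) * row_vars(unclass(experimental))) / df
  expressed <- rowMeans(cbind(unclass(control), unclass(experimental))) >
    expressed_threshold
  anchor_set <- vw[expressed]
  if (!length(anchor_set)) anchor_set <- vw
  low_q <- anchor_set[anchor_set <= stats::quantile(anchor_set, 0.25)]
  tech_var <- stats::median(low_q) / (stats::qchisq(0.125, df) / df)
  vw / tech_var > stats::qf(1 - alpha_F, df, Inf)
}

#' Welch t-test + Benjamini-Hochberg baseline (comparator)
#'
#' A conventional pipeline kept as a built-in comparator: per-gene Welch
#' t-test, BH adjustment across all genes, and a minimal-fold filter.
#'
#' @param control,experimental aligned normalized [expr_matrix()] objects.
#' @param alpha BH-adjusted significance level (default 0.05).
#' @param fold_min minimal fold (default 1.5), computed as in the
#'   associative pipeline.
#' @return a `data.frame` of class `de_result` with columns `gene_id`,
#'   `mean_control`, `mean_experimental`, `fold`, `p_value`, `p_adj`,
#'   `selected`, `direction`, `reasons_rejected`.
#' @export
ttest_bh_baseline <- function(control, experimental, alpha = 0.05,
                              fold_min = 1.5) {
  validate_expr_matrix(control)
  validate_expr_matrix(experimental)
  check_gene_alignment(rownames(control), rownames(experimental),
                       "control and experimental matrices")
  n1 <- ncol(control); n2 <- ncol(experimental)
  m1 <- rowMeans(control); m2 <- rowMeans(experimental)
  v1 <- row_vars(unclass(control)); v2 <- row_vars(unclass(experimental))
  se2 <- v1 / n1 + v2 / n2
  t_stat <- (m2 - m1) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t_stat), df = df)
  degenerate <- se2 == 0
  p[degenerate] <- ifelse(m1[degenerate] == m2[degenerate], 1, 0)
  p_adj <- stats::p.adjust(p, method = "BH")
  fold <- fold_from_means(m1, m2)
  selected <- p_adj < alpha & fold >= fold_min
  reasons <- character(length(p))
  reasons[!selected] <- paste0(ifelse(p_adj[!selected] >= alpha, "p_adj", ""),
                               ifelse(fold[!selected] < fold_min, ",fold", ""))
  reasons <- sub("^,", "", reasons)
  result <- data.frame(
    gene_id = rownames(control),
    mean_control = m1, mean_experimental = m2, fold = fold,
    p_value = p, p_adj = p_adj, selected = selected,
    direction = ifelse(selected, ifelse(m2 > m1, "up", "down"), "none"),
    reasons_rejected = reasons,
    row.names = NULL, stringsAsFactors = FALSE
  )
  class(result) <- c("de_result", class(result))
  result
}

#' @export
print.de_result <- function(x, ...) {
  cat(sprintf("<de_result> %d genes, %d selected (%d up, %d down)\n",
              nrow(x), sum(x$selected), sum(x$direction == "up"),
              sum(x$direction == "down")))
  invisible(x)
}
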