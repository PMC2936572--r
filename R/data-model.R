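#' Construct an expression matrix
#'
#' The package's universal currency: a numeric gene x sample matrix of
#' non-negative (raw) or background-SD-unit (normalized) intensities, with
#' unique gene identifiers as rownames and unique sample identifiers as
#' colnames. The `sorted_by_mean` attribute records whether rows are ordered
#' by non-increasing average expression.
#'
#' @param values numeric matrix (genes in rows, samples in columns) with
#'   complete dimnames.
#' @param sorted_by_mean logical; declare the rows sorted by non-increasing
#'   row mean. Verified, not trusted.
#' @return a validated matrix of class `expr_matrix`.
#' @export
expr_matrix <- function(values, sorted_by_mean = FALSE) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  attr(values, "sorted_by_mean") <- isTRUE(sorted_by_mean)
  class(values) <- c("expr_matrix", class(matrix()))
  validate_expr_matrix(values)
  values
}

#' Validate an expression matrix
#'
#' Checks the structural invariants: at least 2 genes and 2 samples, unique
#' non-missing identifiers, finite values, and (when flagged) row means
#' non-increasing.
#'
#' @param m matrix to validate.
#' @return `m`, invisibly. Errors describe the first violated invariant.
#' @export
validate_expr_matrix <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) {
    stop("expression matrix must be a numeric matrix", call. = FALSE)
  }
  if (nrow(m) < 2L || ncol(m) < 2L) {
    stop("expression matrix needs at least 2 genes and 2 samples, got ",
         nrow(m), " x ", ncol(m), call. = FALSE)
  }
  gid <- rownames(m)
  sid <- colnames(m)
  if (is.null(gid) || is.null(sid) || anyNA(gid) || anyNA(sid) ||
      any(gid == "") || any(sid == "")) {
    stop("expression matrix must carry non-empty gene and sample identifiers",
         call. = FALSE)
  }
  if (anyDuplicated(gid)) {
    stop("duplicate gene identifier: ", gid[duplicated(gid)][1L], call. = FALSE)
  }
  if (anyDuplicated(sid)) {
    stop("duplicate sample identifier: ", sid[duplicated(sid)][1L], call. = FALSE)
  }
  if (any(!is.finite(m))) {
    bad <- which(!is.finite(m), arr.ind = TRUE)[1L, ]
    stop("non-finite value at gene '", gid[bad[1L]], "', sample '",
         sid[bad[2L]], "'", call. = FALSE)
  }
  # NOTE: the sorted_by_mean flag records provenance (rows are in the sort
  # order established on the full sample group); subgroup matrices inherit
  # that order but their own row means need not be monotone, so monotonicity
  # is guaranteed by sort_by_mean() rather than re-checked here.
  invisible(m)
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples%s\n", nrow(x), ncol(x),
              if (isTRUE(attr(x, "sorted_by_mean"))) ", sorted by mean" else ""))
  cat("value range:", format(range(x), digits = 4), "\n")
  invisible(x)
}

# Re-wrap a plain matrix as expr_matrix, carrying a sorted flag.
as_expr_matrix <- function(values, sorted_by_mean = FALSE) {
  expr_matrix(as.matrix(unclass(values)), sorted_by_mean = sorted_by_mean)
}

#' Construct a truth table of injected changes
#'
#' Per-gene ground-truth labels for a benchmark: `up` (multiplied by the
#' injected fold), `down` (divided by it) or `unchanged`, plus the fold
#' factor itself (1 for unchanged genes).
#'
#' @param gene_id character vector of gene identifiers (unique).
#' @param label character vector in `c("up", "down", "unchanged")`.
#' @param fold positive numeric vector; must be 1 exactly iff unchanged.
#' @return a `data.frame` of class `truth_table`.
#' @export
truth_table <- function(gene_id, label, fold) {
  label <- as.character(label)
  if (length(gene_id) != length(label) || length(label) != length(fold)) {
    stop("gene_id, label and fold must have equal length", call. = FALSE)
  }
  if (anyDuplicated(gene_id)) {
    stop("duplicate gene identifier in truth table: ",
         gene_id[duplicated(gene_id)][1L], call. = FALSE)
  }
  if (!all(label %in% c("up", "down", "unchanged"))) {
    stop("labels must be 'up', 'down' or 'unchanged'", call. = FALSE)
  }
  if (any(!is.finite(fold)) || any(fold <= 0)) {
    stop("fold factors must be positive and finite", call. = FALSE)
  }
  if (!all((label == "unchanged") == (fold == 1))) {
    stop("fold must equal 1 exactly iff the label is 'unchanged'", call. = FALSE)
  }
  structure(
    data.frame(gene_id = as.character(gene_id), label = label, fold = fold,
               stringsAsFactors = FALSE),
    class = c("truth_table", "data.frame")
  )
}

#' Analysis restrictions for DE selection
#'
#' The selection gates applied after the statistical tests: a minimal
#' fold-change restriction `Fa` (> 1, dimensionless), a minimal expression
#' level `Em` (background-SD units, applied to the larger of the two group
#' means), the Student-filter significance level, and the family-wise level
#' of the associative test (Bonferroni-divided by the number of genes
#' tested). Defaults are the Fa = 1.5, Em = 20 working point used throughout
#' the benchmark figures, with alpha 0.05 for both tests.
#'
#' @param Fa minimal fold change, > 1.
#' @param Em minimal expression level in background-SD units, >= 0.
#' @param alpha_student significance level of the per-gene Student filter.
#' @param alpha_assoc family-wise significance level of the associative test.
#' @return a list of class `analysis_restrictions`.
#' @export
analysis_restrictions <- function(Fa = 1.5, Em = 20, alpha_student = 0.05,
                                  alpha_assoc = 0.05) {
  if (!is.numeric(Fa) || length(Fa) != 1L || Fa <= 1) {
    stop("Fa must be a single number > 1", call. = FALSE)
  }
  if (!is.numeric(Em) || length(Em) != 1L || Em < 0) {
    stop("Em must be a single number >= 0", call. = FALSE)
  }
  if (alpha_student <= 0 || alpha_student >= 1) {
    stop("alpha_student must lie in (0, 1)", call. = FALSE)
  }
  if (alpha_assoc <= 0 || alpha_assoc >= 1) {
    stop("alpha_assoc must lie in (0, 1)", call. = FALSE)
  }
  structure(list(Fa = Fa, Em = Em, alpha_student = alpha_student,
                 alpha_assoc = alpha_assoc),
            class = "analysis_restrictions")
}

#' Injection design for controlled fold changes
#'
#' Describes how ground-truth changes are spread over a mean-sorted matrix:
#' consecutive blocks of `block_size` genes each receive `fraction` modified
#' genes (half multiplied by `Fd`, half divided, in balanced mode), and the
#' top block is sub-divided into finer blocks of `top_block_split` genes so
#' that the widest part of the dynamic range is probed in more detail.
#'
#' @param Fd fold change to introduce, > 1 (ignored in custom mode).
#' @param fraction total fraction of genes modified, in (0, 1).
#' @param mode one of `"balanced"`, `"asymmetric_up"`, `"custom"`.
#' @param block_size genes per block (default 1000).
#' @param top_block_split sub-block size within the top block (default 200);
#'   must divide `block_size`.
#' @param placement `"top_of_block"` (highest-mean genes of each block are
#'   modified, up labels first) or `"random"` (seeded).
#' @param placement_seed integer seed for random placement.
#' @param up_fraction,down_fraction,fold_up,fold_down custom-mode settings.
#' @return a list of class `injection_design`.
#' @export
injection_design <- function(Fd = 2, fraction = 0.20,
                             mode = c("balanced", "asymmetric_up", "custom"),
                             block_size = 1000L, top_block_split = 200L,
                             placement = c("top_of_block", "random"),
                             placement_seed = NULL,
                             up_fraction = NULL, down_fraction = NULL,
                             fold_up = NULL, fold_down = NULL) {
  mode <- match.arg(mode)
  placement <- match.arg(placement)
  block_size <- as.integer(block_size)
  top_block_split <- as.integer(top_block_split)
  if (block_size < 1L || top_block_split < 1L ||
      block_size %% top_block_split != 0L) {
    stop("block_size must be a positive multiple of top_block_split",
         call. = FALSE)
  }
  if (mode == "custom") {
    if (is.null(up_fraction) || is.null(down_fraction) ||
        is.null(fold_up) || is.null(fold_down)) {
      stop("custom mode requires up_fraction, down_fraction, fold_up, fold_down",
           call. = FALSE)
    }
    if (fold_up <= 1 || fold_down <= 1) {
      stop("custom fold factors must be > 1", call. = FALSE)
    }
    fraction <- up_fraction + down_fraction
  } else {
    if (!is.numeric(Fd) || length(Fd) != 1L || Fd <= 1) {
      stop("Fd must be a single fold change > 1", call. = FALSE)
    }
    up_fraction <- if (mode == "balanced") fraction / 2 else fraction
    down_fraction <- if (mode == "balanced") fraction / 2 else 0
    fold_up <- Fd
    fold_down <- Fd
  }
  if (fraction <= 0 || fraction >= 1) {
    stop("fraction of modified genes must lie in (0, 1)", call. = FALSE)
  }
  structure(list(Fd = Fd, fraction = fraction, mode = mode,
                 block_size = block_size, top_block_split = top_block_split,
                 placement = placement, placement_seed = placement_seed,
                 up_fraction = up_fraction, down_fraction = down_fraction,
                 fold_up = fold_up, fold_down = fold_down),
            class = "injection_design")
}

# Matrix/truth alignment: identity of gene ids in identical order.
check_gene_alignment <- function(ids_a, ids_b, what = "objects") {
  if (length(ids_a) != length(ids_b) || !all(ids_a == ids_b)) {
    stop("gene identifiers of ", what, " do not agree (same ids, same order, ",
         "are required)", call. = FALSE)
  }
  invisible(TRUE)
}
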