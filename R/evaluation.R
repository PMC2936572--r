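#' Confusion counts against the injected truth
#'
#' Compares a DE result with the truth table: TP are selected genes whose
#' truth label is up/down (and, with `direction_strict`, whose selected
#' direction matches); FN are modified genes not (correctly) selected; FP
#' are unmodified genes selected; TN are unmodified genes not selected. A
#' selected modified gene with the wrong direction is counted as both an FN
#' (its change was missed) and, under the strict convention, an FP; such
#' genes are also reported separately as `direction_errors`.
#'
#' An optional `eligible` mask restricts the evaluated gene universe (e.g.
#' to genes meeting the expression restriction, or to genes kept after
#' hypervariable exclusion); excluded genes are counted in `n_excluded`.
#'
#' @param result a `de_result` (needs `gene_id`, `selected`, `direction`).
#' @param truth the matching [truth_table()].
#' @param direction_strict require the selected direction to match the
#'   injected one (default `TRUE`).
#' @param eligible logical mask of genes in the evaluation universe, or
#'   `NULL` for all genes.
#' @return a list of class `confusion_counts`: `TP`, `FP`, `TN`, `FN`,
#'   `direction_errors`, `n_eligible`, `n_excluded`.
#' @export
confusion <- function(result, truth, direction_strict = TRUE,
                      eligible = NULL) {
  stopifnot(inherits(truth, "truth_table"))
  check_gene_alignment(result$gene_id, truth$gene_id,
                       "DE result and truth table")
  G <- nrow(truth)
  if (is.null(eligible)) eligible <- rep(TRUE, G)
  stopifnot(length(eligible) == G)

  modified <- truth$label != "unchanged" & eligible
  unmodified <- truth$label == "unchanged" & eligible
  sel <- result$selected & eligible
  dir_ok <- result$direction == truth$label

  dir_err <- sum(sel & modified & !dir_ok)
  TP <- if (direction_strict) sum(sel & modified & dir_ok) else
    sum(sel & modified)
  FN <- sum(modified) - TP
  FP <- sum(sel & unmodified) + if (direction_strict) dir_err else 0L
  TN <- sum(unmodified & !sel)
  structure(list(TP = TP, FP = FP, TN = TN, FN = FN,
                 direction_errors = dir_err,
                 n_eligible = sum(eligible), n_excluded = sum(!eligible)),
            class = "confusion_counts")
}

#' Sensitivity, Specificity and Precision from confusion counts
#'
#' `sensitivity = TP / (TP + FN)`, `specificity = TN / (TN + FP)`,
#' `precision = TP / (TP + FP)`; a 0/0 ratio is reported as `NA`.
#'
#' @param counts a [confusion()] result.
#' @return named numeric vector `c(sensitivity, specificity, precision)`.
#' @export
classification_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  c(sensitivity = ratio(counts$TP, counts$TP + counts$FN),
    specificity = ratio(counts$TN, counts$TN + counts$FP),
    precision   = ratio(counts$TP, counts$TP + counts$FP))
}

#' @export
print.confusion_counts <- function(x, ...) {
  m <- classification_metrics(x)
  cat(sprintf("<confusion_counts> TP %d  FP %d  TN %d  FN %d (eligible %d, excluded %d)\n",
              x$TP, x$FP, x$TN, x$FN, x$n_eligible, x$n_excluded))
  cat(sprintf("  sensitivity %.4g  specificity %.4g  precision %.4g\n",
              m["sensitivity"], m["specificity"], m["precision"]))
  invisible(x)
}

# Consecutive block index for G sorted genes split into n_blocks equal
# blocks; the last block absorbs any remainder.
block_index <- function(G, n_blocks) {
  size <- G %/% n_blocks
  idx <- pmin(((seq_len(G) - 1L) %/% size) + 1L, n_blocks)
  idx
}

# Percent-interval label of block i (1 = highest expression) out of n.
block_label <- function(i, n_blocks) {
  upper <- round(100 * (n_blocks - i + 1L) / n_blocks)
  lower <- round(100 * (n_blocks - i) / n_blocks)
  sprintf("%d-%d", lower, upper)
}

#' Block-wise performance profile over the expression range
#'
#' Partitions the genes -- which must be in the benchmark's sorted order,
#' highest expression first -- into `n_blocks` equal consecutive blocks and
#' computes confusion counts and metrics per block and overall. Block
#' labels are percentile intervals along the decreasingly sorted data
#' ("95-100" is the top 5% when `n_blocks = 20`).
#'
#' @param result a `de_result` in sorted gene order.
#' @param truth the matching [truth_table()].
#' @param n_blocks number of equal blocks (default 20).
#' @param direction_strict passed to [confusion()].
#' @param eligible optional logical universe mask, as in [confusion()].
#' @return list of class `metric_series`: `blocks` (a `data.frame` with
#'   per-block counts and metrics), `overall` (a `confusion_counts`),
#'   `overall_metrics`.
#' @export
blockwise_metrics <- function(result, truth, n_blocks = 20L,
                              direction_strict = TRUE, eligible = NULL) {
  stopifnot(inherits(truth, "truth_table"))
  G <- nrow(truth)
  if (is.null(eligible)) eligible <- rep(TRUE, G)
  bi <- block_index(G, n_blocks)
  rows <- lapply(seq_len(n_blocks), function(i) {
    in_block <- bi == i
    cnt <- confusion(result[in_block, , drop = FALSE],
                     truth_from_subset(truth, in_block),
                     direction_strict = direction_strict,
                     eligible = eligible[in_block])
    met <- classification_metrics(cnt)
    data.frame(block = i, label = block_label(i, n_blocks),
               n_genes = sum(in_block), n_eligible = cnt$n_eligible,
               TP = cnt$TP, FP = cnt$FP, TN = cnt$TN, FN = cnt$FN,
               sensitivity = met["sensitivity"],
               specificity = met["specificity"],
               precision = met["precision"],
               row.names = NULL, stringsAsFactors = FALSE)
  })
  overall <- confusion(result, truth, direction_strict = direction_strict,
                       eligible = eligible)
  structure(list(blocks = do.call(rbind, rows),
                 overall = overall,
                 overall_metrics = classification_metrics(overall),
                 n_blocks = n_blocks),
            class = "metric_series")
}

# subset a truth table, keeping the class
truth_from_subset <- function(truth, mask) {
  structure(truth[mask, , drop = FALSE],
            class = c("truth_table", "data.frame"))
}

#' @export
print.metric_series <- function(x, ...) {
  m <- x$overall_metrics
  cat(sprintf("<metric_series> %d blocks; overall sensitivity %.3f, precision %.3f\n",
              x$n_blocks, m["sensitivity"], m["precision"]))
  invisible(x)
}

# Run one benchmark repeat through a normalization + DE chain. Both
# subgroups are normalized jointly (as real analyses normalize all arrays
# together), then the chain's DE method is applied and scored. When
# `restrict_to_em` is TRUE the evaluation universe is the set of genes
# meeting the expression restriction (max of the two group means >= Em on
# the normalized scale): genes the restrictions exclude a priori are
# evaluated as out of reach rather than as misses, which is what makes
# sensitivity respond to Em the way the benchmark's figures show.
run_chain_once <- function(bench, normalizer, de_method, restrictions,
                           n_blocks = 20L, direction_strict = TRUE,
                           restrict_to_em = TRUE, sample_cols = NULL) {
  ctrl <- bench$control
  expe <- bench$experimental
  if (!is.null(sample_cols)) {
    ctrl <- as_expr_matrix(unclass(ctrl)[, sample_cols$control, drop = FALSE],
                           sorted_by_mean = TRUE)
    expe <- as_expr_matrix(unclass(expe)[, sample_cols$experimental, drop = FALSE],
                           sorted_by_mean = TRUE)
  }
  pooled <- as_expr_matrix(cbind(unclass(ctrl), unclass(expe)),
                           sorted_by_mean = TRUE)
  norm <- get_normalizer(normalizer)(pooled)
  nc <- ncol(ctrl)
  ctrl_n <- as_expr_matrix(unclass(norm)[, seq_len(nc), drop = FALSE],
                           sorted_by_mean = TRUE)
  expe_n <- as_expr_matrix(unclass(norm)[, nc + seq_len(ncol(expe)), drop = FALSE],
                           sorted_by_mean = TRUE)
  result <- get_de_method(de_method)(ctrl_n, expe_n, restrictions)
  eligible <- if (restrict_to_em) {
    pmax(rowMeans(ctrl_n), rowMeans(expe_n)) >= restrictions$Em
  } else {
    NULL
  }
  blockwise_metrics(result, bench$truth, n_blocks = n_blocks,
                    direction_strict = direction_strict, eligible = eligible)
}

# mean and SD across repeats of a numeric vector per repeat
mean_sd_rows <- function(mat) {
  list(mean = rowMeans(mat, na.rm = TRUE),
       sd = apply(mat, 1L, stats::sd, na.rm = TRUE))
}

#' Evaluate a normalization + DE chain over repeated benchmarks
#'
#' For each of `n_repeats` repeats: build a benchmark with a fresh sample
#' permutation (seeds `base_seed + 0:(n-1)`), normalize both subgroups
#' jointly with the chosen normalizer, run the DE method, and score
#' block-wise against the injected truth. Reports mean and SD of
#' Sensitivity and Precision per block and overall across the repeats.
#'
#' @param matrix an [expr_matrix()] of a homogeneous sample group.
#' @param design an [injection_design()].
#' @param normalizer registered normalizer name (or a callable).
#' @param de_method registered DE method name (or a callable).
#' @param restrictions an [analysis_restrictions()].
#' @param n_repeats number of permutation repeats (default 3).
#' @param base_seed first split seed.
#' @param n_blocks blocks for the expression-level profile (default 20).
#' @param direction_strict passed to [confusion()].
#' @param restrict_to_em evaluate over the genes meeting the `Em`
#'   restriction (default `TRUE`); set `FALSE` to score against every gene.
#' @return list of class `repeat_evaluation`: `blocks` (per-block mean/SD
#'   of sensitivity and precision), `overall` (mean/SD of the overall
#'   metrics), `repeats` (the individual `metric_series`), `n_repeats`.
#' @export
evaluate_repeats <- function(matrix, design = injection_design(),
                             normalizer = "two_step",
                             de_method = "associative",
                             restrictions = analysis_restrictions(),
                             n_repeats = 3L, base_seed = 1L, n_blocks = 20L,
                             direction_strict = TRUE, restrict_to_em = TRUE) {
  benches <- replicate_benchmarks(matrix, design, n_repeats, base_seed)
  runs <- lapply(benches, run_chain_once, normalizer = normalizer,
                 de_method = de_method, restrictions = restrictions,
                 n_blocks = n_blocks, direction_strict = direction_strict,
                 restrict_to_em = restrict_to_em)
  sens <- vapply(runs, function(r) r$blocks$sensitivity, numeric(n_blocks))
  prec <- vapply(runs, function(r) r$blocks$precision, numeric(n_blocks))
  sens <- matrix(sens, nrow = n_blocks)
  prec <- matrix(prec, nrow = n_blocks)
  s <- mean_sd_rows(sens)
  p <- mean_sd_rows(prec)
  blocks <- data.frame(block = seq_len(n_blocks),
                       label = vapply(seq_len(n_blocks), block_label,
                                      character(1L), n_blocks = n_blocks),
                       sensitivity_mean = s$mean, sensitivity_sd = s$sd,
                       precision_mean = p$mean, precision_sd = p$sd,
                       stringsAsFactors = FALSE)
  ov <- vapply(runs, function(r) r$overall_metrics, numeric(3L))
  overall <- data.frame(metric = rownames(ov),
                        mean = rowMeans(ov, na.rm = TRUE),
                        sd = apply(ov, 1L, stats::sd, na.rm = TRUE),
                        row.names = NULL, stringsAsFactors = FALSE)
  structure(list(blocks = blocks, overall = overall, repeats = runs,
                 n_repeats = n_repeats, design = design,
                 restrictions = restrictions, base_seed = base_seed,
                 normalizer = if (is.character(normalizer)) normalizer else "custom",
                 de_method = if (is.character(de_method)) de_method else "custom"),
            class = "repeat_evaluation")
}

#' @export
print.repeat_evaluation <- function(x, ...) {
  s <- x$overall[x$overall$metric == "sensitivity", ]
  p <- x$overall[x$overall$metric == "precision", ]
  cat(sprintf("<repeat_evaluation> %s + %s, %d repeats\n  sensitivity %.3f +/- %.3f   precision %.3f +/- %.3f\n",
              x$normalizer, x$de_method, x$n_repeats,
              s$mean, s$sd, p$mean, p$sd))
  invisible(x)
}

#' Replicate-number power analysis
#'
#' For each requested number of replicates n, draws `n_boot` benchmarks
#' (fresh sample permutation each), subsamples n arrays per subgroup
#' without replacement, runs the chain, and records overall Sensitivity and
#' Precision; reported as mean and SD over the `n_boot` repeats. With
#' `n = S/2` the subsample is the full subgroup and the numbers coincide
#' with [evaluate_repeats()].
#'
#' @inheritParams evaluate_repeats
#' @param n_list numbers of replicates per subgroup to test (default 2:10).
#' @param n_boot repeats per n (default 3).
#' @return list of class `power_curve` with a `curve` data.frame
#'   (`n`, `sensitivity_mean/sd`, `precision_mean/sd`).
#' @export
power_analysis <- function(matrix, design = injection_design(),
                           normalizer = "two_step",
                           de_method = "associative",
                           restrictions = analysis_restrictions(),
                           n_list = 2:10, n_boot = 3L, base_seed = 1L,
                           direction_strict = TRUE, restrict_to_em = TRUE) {
  S2 <- ncol(matrix) %/% 2L
  if (max(n_list) > S2) {
    stop("n_list exceeds the subgroup size (", S2, ")", call. = FALSE)
  }
  if (any(n_list < 2L)) stop("need at least 2 replicates per subgroup",
                             call. = FALSE)
  benches <- replicate_benchmarks(matrix, design, n_boot, base_seed)
  rows <- lapply(n_list, function(n) {
    met <- vapply(seq_len(n_boot), function(b) {
      set.seed(base_seed + 1000L * b + n)
      cols <- list(control = sort(sample.int(S2, n)),
                   experimental = sort(sample.int(S2, n)))
      run <- run_chain_once(benches[[b]], normalizer, de_method, restrictions,
                            direction_strict = direction_strict,
                            restrict_to_em = restrict_to_em,
                            sample_cols = cols)
      run$overall_metrics[c("sensitivity", "precision")]
    }, numeric(2L))
    data.frame(n = n,
               sensitivity_mean = mean(met[1L, ], na.rm = TRUE),
               sensitivity_sd = stats::sd(met[1L, ]),
               precision_mean = mean(met[2L, ], na.rm = TRUE),
               precision_sd = stats::sd(met[2L, ]))
  })
  structure(list(curve = do.call(rbind, rows), design = design,
                 restrictions = restrictions, n_boot = n_boot,
                 base_seed = base_seed),
            class = "power_curve")
}

#' @export
print.power_curve <- function(x, ...) {
  cat("<power_curve>\n")
  print(format(x$curve, digits = 3), row.names = FALSE)
  invisible(x)
}
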