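#' Sort a matrix by average expression
#'
#' Reorders rows so row means are non-increasing (stable: ties keep their
#' input order) and sets the `sorted_by_mean` flag. Block-wise injection and
#' block-wise evaluation both operate on this order.
#'
#' @param matrix an [expr_matrix()].
#' @return the sorted [expr_matrix()].
#' @export
sort_by_mean <- function(matrix) {
  validate_expr_matrix(matrix)
  ord <- order(-rowMeans(matrix))  # radix order is stable for ties
  as_expr_matrix(unclass(matrix)[ord, , drop = FALSE], sorted_by_mean = TRUE)
}

#' Split samples into control and experimental subgroups
#'
#' Randomly permutes the sample order with the given seed (or keeps the
#' original order when `permutation_seed` is `NULL`), then assigns the first
#' half of the samples to the control subgroup and the second half to the
#' experimental subgroup. Gene order is untouched.
#'
#' @param matrix an [expr_matrix()] with an even number of samples.
#' @param permutation_seed integer seed, or `NULL` for the original order.
#' @return list with elements `control` and `experimental`.
#' @export
split_group <- function(matrix, permutation_seed = NULL) {
  validate_expr_matrix(matrix)
  S <- ncol(matrix)
  if (S %% 2L != 0L) {
    stop("the sample count (", S, ") is odd; drop one sample before splitting",
         call. = FALSE)
  }
  idx <- seq_len(S)
  if (!is.null(permutation_seed)) {
    set.seed(as.integer(permutation_seed))
    idx <- sample(idx)
  }
  sorted <- isTRUE(attr(matrix, "sorted_by_mean"))
  ctrl <- unclass(matrix)[, idx[seq_len(S / 2L)], drop = FALSE]
  expe <- unclass(matrix)[, idx[seq_len(S / 2L) + S / 2L], drop = FALSE]
  list(control = as_expr_matrix(ctrl, sorted_by_mean = sorted),
       experimental = as_expr_matrix(expe, sorted_by_mean = sorted))
}

# Pick the modified rows within one block (indices into the block, which is
# itself in sorted order): highest-mean genes take up labels first, the next
# tier down labels; random placement draws from the block instead.
place_in_block <- function(block_len, n_up, n_down, placement) {
  if (placement == "top_of_block") {
    list(up = seq_len(n_up),
         down = if (n_down > 0L) n_up + seq_len(n_down) else integer(0))
  } else {
    pick <- sample.int(block_len, n_up + n_down)
    list(up = pick[seq_len(n_up)],
         down = if (n_down > 0L) pick[n_up + seq_len(n_down)] else integer(0))
  }
}

#' Inject controlled fold changes into a sorted matrix
#'
#' Partitions the genes (in sorted order) into consecutive blocks of
#' `design$block_size`; the top block is sub-partitioned into blocks of
#' `design$top_block_split` genes. Within each (sub-)block, the designed
#' fraction of genes is multiplied by the up fold across every sample
#' (label `up`) and a disjoint fraction divided by the down fold (label
#' `down`). All other values are bit-identical to the input. A trailing
#' partial block receives proportionally scaled counts, rounded down.
#'
#' @param experimental an [expr_matrix()] flagged `sorted_by_mean`.
#' @param design an [injection_design()].
#' @return list with elements `modified` (the matrix with changes) and
#'   `truth` (the [truth_table()]).
#' @export
inject_changes <- function(experimental, design = injection_design()) {
  validate_expr_matrix(experimental)
  stopifnot(inherits(design, "injection_design"))
  if (!isTRUE(attr(experimental, "sorted_by_mean"))) {
    stop("inject_changes requires a matrix sorted by mean (see sort_by_mean)",
         call. = FALSE)
  }
  G <- nrow(experimental)
  bs <- design$block_size
  if (G < bs) {
    stop("matrix has fewer genes (", G, ") than one block (", bs, ")",
         call. = FALSE)
  }
  if (design$mode == "balanced") {
    for (unit in c(bs, design$top_block_split)) {
      if (abs(design$fraction * unit - round(design$fraction * unit)) > 1e-9 ||
          round(design$fraction * unit) %% 2L != 0L) {
        stop("balanced mode needs fraction x ", unit,
             " to be an even integer", call. = FALSE)
      }
    }
  }
  if (!is.null(design$placement_seed)) set.seed(as.integer(design$placement_seed))

  # block layout: five-fold (by default) finer sub-blocks first, then
  # ordinary blocks, then a possibly partial trailing block
  starts <- c(seq(1L, bs, by = design$top_block_split),
              if (G > bs) seq(bs + 1L, G, by = bs) else integer(0))
  ends <- c(starts[-1L] - 1L, G)

  up_idx <- integer(0)
  down_idx <- integer(0)
  for (k in seq_along(starts)) {
    len <- ends[k] - starts[k] + 1L
    n_up <- floor(design$up_fraction * len + 1e-9)
    n_down <- floor(design$down_fraction * len + 1e-9)
    pl <- place_in_block(len, n_up, n_down, design$placement)
    up_idx <- c(up_idx, starts[k] - 1L + pl$up)
    down_idx <- c(down_idx, starts[k] - 1L + pl$down)
  }

  values <- unclass(experimental)
  values[up_idx, ] <- values[up_idx, , drop = FALSE] * design$fold_up
  values[down_idx, ] <- values[down_idx, , drop = FALSE] / design$fold_down

  label <- rep("unchanged", G)
  label[up_idx] <- "up"
  label[down_idx] <- "down"
  fold <- rep(1, G)
  fold[up_idx] <- design$fold_up
  fold[down_idx] <- design$fold_down

  list(modified = as_expr_matrix(values, sorted_by_mean = FALSE),
       truth = truth_table(rownames(experimental), label, fold))
}

#' Build a ground-truth benchmark from a homogeneous matrix
#'
#' Composition of [sort_by_mean()], [split_group()] and [inject_changes()]:
#' the control subgroup is left untouched, the experimental subgroup
#' receives the designed fold changes.
#'
#' @param matrix an [expr_matrix()] of a presumed-homogeneous sample group.
#' @param design an [injection_design()].
#' @param permutation_seed seed for the sample split (`NULL`: original order).
#' @return a list of class `benchmark_dataset` with elements `control`,
#'   `experimental`, `truth`, `design`, `permutation_seed`.
#' @export
make_benchmark <- function(matrix, design = injection_design(),
                           permutation_seed = NULL) {
  sorted <- sort_by_mean(matrix)
  halves <- split_group(sorted, permutation_seed)
  inj <- inject_changes(halves$experimental, design)
  structure(list(control = halves$control,
                 experimental = inj$modified,
                 truth = inj$truth,
                 design = design,
                 permutation_seed = permutation_seed),
            class = "benchmark_dataset")
}

#' @export
print.benchmark_dataset <- function(x, ...) {
  n_up <- sum(x$truth$label == "up")
  n_down <- sum(x$truth$label == "down")
  cat(sprintf("<benchmark_dataset> %d genes, %d + %d samples; %d up + %d down injected (%s, Fd up %.3g / down %.3g)\n",
              nrow(x$control), ncol(x$control), ncol(x$experimental),
              n_up, n_down, x$design$mode, x$design$fold_up, x$design$fold_down))
  invisible(x)
}

#' Replicate a benchmark with fresh sample permutations
#'
#' Builds `n_repeats` benchmarks with split seeds `base_seed + 0:(n-1)`, the
#' repetition scheme used to report mean and SD of the quality metrics.
#'
#' @param matrix an [expr_matrix()].
#' @param design an [injection_design()].
#' @param n_repeats number of repeats (>= 1).
#' @param base_seed integer; repeat i uses split seed `base_seed + i - 1`.
#' @return list of `benchmark_dataset` objects.
#' @export
replicate_benchmarks <- function(matrix, design = injection_design(),
                                 n_repeats = 3L, base_seed = 1L) {
  if (n_repeats < 1L) stop("n_repeats must be >= 1", call. = FALSE)
  lapply(seq_len(n_repeats) - 1L, function(i) {
    make_benchmark(matrix, design, permutation_seed = base_seed + i)
  })
}
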