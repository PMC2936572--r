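#' Read an expression matrix from delimited text
#'
#' Expects a header row of sample identifiers, gene identifiers in the first
#' column and numeric intensities elsewhere. Row and column order are
#' preserved from the file.
#'
#' @param path path to the file.
#' @param delimiter field separator (default tab).
#' @return an [expr_matrix()].
#' @export
read_matrix <- function(path, delimiter = "\t") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("matrix file has no data rows: ", path, call. = FALSE)
  fields <- strsplit(lines, delimiter, fixed = TRUE)
  header <- fields[[1L]]
  sample_ids <- header[-1L]
  ncols <- length(header)
  body <- fields[-1L]
  widths <- lengths(body)
  if (any(widths != ncols)) {
    bad <- which(widths != ncols)[1L]
    stop("ragged row ", bad + 1L, ": expected ", ncols, " fields, found ",
         widths[bad], call. = FALSE)
  }
  gene_ids <- vapply(body, `[[`, character(1L), 1L)
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene identifier: ", gene_ids[duplicated(gene_ids)][1L],
         call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample identifier: ", sample_ids[duplicated(sample_ids)][1L],
         call. = FALSE)
  }
  num <- suppressWarnings(
    vapply(body, function(f) as.numeric(f[-1L]), numeric(length(sample_ids)))
  )
  # vapply returns samples x genes for >1 sample; normalize orientation
  num <- matrix(num, nrow = length(sample_ids))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop("non-numeric value at row ", bad[2L] + 1L, " (gene '",
         gene_ids[bad[2L]], "'), column ", bad[1L] + 1L, " (sample '",
         sample_ids[bad[1L]], "')", call. = FALSE)
  }
  values <- t(num)
  dimnames(values) <- list(gene_ids, sample_ids)
  expr_matrix(values)
}

#' Write an expression matrix as tab-delimited text
#'
#' Produces a UTF-8 TSV with header `gene_id<TAB>sample...`; values are
#' rendered with 15 significant digits so a read/write round trip is the
#' identity well beyond 12 significant digits.
#'
#' @param matrix an [expr_matrix()] (or validatable numeric matrix).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_matrix <- function(matrix, path) {
  validate_expr_matrix(matrix)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("gene_id", colnames(matrix)), collapse = "\t"), con)
  body <- apply(format(unclass(matrix), digits = 15, scientific = FALSE,
                       trim = TRUE), 1L, paste, collapse = "\t")
  writeLines(paste(rownames(matrix), body, sep = "\t"), con)
  invisible(path)
}

#' Read a truth table
#'
#' Three tab-separated columns: gene identifier, modification code
#' (0 unchanged, 1 increased, 2 decreased -- the convention of the
#' benchmark's distributed truth files) and the fold factor.
#'
#' @param path path to the file.
#' @return a [truth_table()].
#' @export
read_truth <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "integer", "numeric"))
  if (ncol(df) != 3L) {
    stop("truth table must have 3 columns (gene_id, code, fold), found ",
         ncol(df), call. = FALSE)
  }
  code <- df[[2L]]
  if (any(!code %in% 0:2)) {
    stop("modification code outside {0, 1, 2}: ",
         code[!code %in% 0:2][1L], call. = FALSE)
  }
  fold <- df[[3L]]
  if (any(!is.finite(fold)) || any(fold <= 0)) {
    stop("fold factors must be positive", call. = FALSE)
  }
  label <- c("unchanged", "up", "down")[code + 1L]
  truth_table(df[[1L]], label, fold)
}

#' Write a truth table
#'
#' Inverse of [read_truth()]: columns gene_id, code (0/1/2 for
#' unchanged/up/down) and fold.
#'
#' @param truth a [truth_table()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "truth_table"))
  code <- match(truth$label, c("unchanged", "up", "down")) - 1L
  out <- data.frame(gene_id = truth$gene_id, code = code,
                    fold = format(truth$fold, digits = 15, trim = TRUE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
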