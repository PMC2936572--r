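# SD of a standard normal truncated at +/- a, used to de-bias the trimmed
# estimate: sqrt(1 - 2*a*dnorm(a) / (2*pnorm(a) - 1)). For a = 3 this is
# ~0.986583.
truncnorm_sd_factor <- function(a) {
  sqrt(1 - 2 * a * stats::dnorm(a) / (2 * stats::pnorm(a) - 1))
}

#' Fit the background distribution of one array
#'
#' Estimates the mean `Av` and standard deviation `SD` of the non-expressed
#' (background) cohort by an iterative trimmed-normal fit: start from the
#' lower half of the sorted intensities, then repeatedly (i) compute the
#' member mean and SD, (ii) de-bias the SD by the known truncated-normal
#' factor for a +/- `trim` SD window, and (iii) re-admit every value inside
#' `Av +/- trim * SD`, until the parameters change by less than `tol`
#' relatively or `max_iter` iterations are reached.
#'
#' @param values numeric vector of one array's intensities (>= 200 values).
#' @param trim trimming window half-width in SD units (default 3).
#' @param tol relative convergence tolerance on (Av, SD) (default 1e-6).
#' @param max_iter iteration cap (default 100).
#' @return a list of class `background_model`: `Av`, `SD`, `member_mask`,
#'   `n_members`, `n_iterations`, `converged`.
#' @export
fit_background <- function(values, trim = 3, tol = 1e-6, max_iter = 100L) {
  if (!is.numeric(values) || length(values) < 200L) {
    stop("fit_background needs at least 200 numeric values", call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("fit_background requires finite values", call. = FALSE)
  }
  corr <- truncnorm_sd_factor(trim)
  n <- length(values)
  members <- values <= stats::median(values)   # lower-half initialization
  av <- mean(values[members])
  sdv <- stats::sd(values[members])
  if (!is.finite(sdv) || sdv == 0) {
    stop("degenerate background: member values have zero spread", call. = FALSE)
  }
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    members <- values >= av - trim * sdv & values <= av + trim * sdv
    if (sum(members) < 50L) {
      stop("degenerate background: fewer than 50 member values at iteration ",
           iter, call. = FALSE)
    }
    av_new <- mean(values[members])
    sd_new <- stats::sd(values[members]) / corr
    if (!is.finite(sd_new) || sd_new == 0) {
      stop("degenerate background: member values have zero spread", call. = FALSE)
    }
    rel <- max(abs(av_new - av) / max(abs(av), 1e-12),
               abs(sd_new - sdv) / sdv)
    av <- av_new
    sdv <- sd_new
    if (rel < tol) {
      converged <- TRUE
      break
    }
  }
  structure(list(Av = av, SD = sdv, member_mask = members,
                 n_members = sum(members), n_iterations = iter,
                 converged = converged),
            class = "background_model")
}

#' @export
print.background_model <- function(x, ...) {
  cat(sprintf("<background_model> Av = %.4g, SD = %.4g (%d members, %d iterations%s)\n",
              x$Av, x$SD, x$n_members, x$n_iterations,
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Standardize each array against its own background (step one)
#'
#' Per array, fits the background with [fit_background()] and transforms
#' `x -> (x - Av) / SD`, so all intensities are expressed in units of the
#' background standard deviation, with the background centred at 0.
#'
#' @param matrix an [expr_matrix()] of raw intensities.
#' @param ... passed on to [fit_background()].
#' @return list with `matrix` (standardized [expr_matrix()]) and `models`
#'   (one `background_model` per array).
#' @export
standardize <- function(matrix, ...) {
  validate_expr_matrix(matrix)
  models <- lapply(seq_len(ncol(matrix)),
                   function(j) fit_background(unclass(matrix)[, j], ...))
  av <- vapply(models, `[[`, numeric(1L), "Av")
  sdv <- vapply(models, `[[`, numeric(1L), "SD")
  std <- sweep(sweep(unclass(matrix), 2L, av, `-`), 2L, sdv, `/`)
  names(models) <- colnames(matrix)
  list(matrix = as_expr_matrix(std,
                               sorted_by_mean = isTRUE(attr(matrix, "sorted_by_mean"))),
       models = models)
}

#' Flag genes expressed above background
#'
#' A gene is called expressed when its mean (across samples, in
#' background-SD units) exceeds the threshold -- by default 3 SD above the
#' background mean, the preliminary criterion separating expressed from
#' non-expressed genes.
#'
#' @param matrix a standardized [expr_matrix()] (background-SD units).
#' @param threshold expression threshold in background-SD units (default 3).
#' @return logical vector, one entry per gene.
#' @export
expressed_mask <- function(matrix, threshold = 3) {
  validate_expr_matrix(matrix)
  rowMeans(matrix) > threshold
}

# One array's robust straight-line fit onto the reference profile:
# iterative OLS with +/- trim * resid_SD re-admission over the equally
# expressed (ee) gene set.
robust_line_fit <- function(y, x, start_mask, trim = 3, max_iter = 100L,
                            min_ee = 30L) {
  corr <- truncnorm_sd_factor(trim)
  ee <- start_mask
  slope <- NA_real_
  intercept <- NA_real_
  rsd <- NA_real_
  for (iter in seq_len(max_iter)) {
    if (sum(ee) < min_ee) {
      stop("fewer than ", min_ee, " equally expressed genes left in the ",
           "regression adjustment", call. = FALSE)
    }
    xm <- mean(x[ee]); ym <- mean(y[ee])
    sxx <- sum((x[ee] - xm)^2)
    if (sxx == 0) stop("degenerate regression: reference values constant",
                       call. = FALSE)
    slope <- sum((x[ee] - xm) * (y[ee] - ym)) / sxx
    if (slope <= 0) {
      stop("non-positive regression slope: array is anti-correlated with ",
           "the reference profile", call. = FALSE)
    }
    intercept <- ym - slope * xm
    resid <- y - intercept - slope * x
    rsd <- stats::sd(resid[ee]) / corr
    keep <- start_mask & abs(resid) <= trim * rsd
    if (identical(keep, ee)) break
    ee <- keep
  }
  list(slope = slope, intercept = intercept, ee_mask = ee, resid_sd = rsd,
       n_iterations = iter)
}

#' Adjust standardized arrays onto a common reference profile (step two)
#'
#' For each array, iteratively fits an ordinary least-squares line of the
#' array against the reference profile over the current equally-expressed
#' gene set (initialized to all expressed genes), trims genes whose residual
#' exceeds `trim` residual SDs, and refits until membership stabilizes. The
#' final map is applied to every gene as `x -> (x - intercept) / slope`, so
#' all arrays end up on the reference scale. Only genes expressed above
#' background participate in the fit.
#'
#' @param matrix a standardized [expr_matrix()] (background-SD units).
#' @param reference `"median"` for the gene-wise median profile across
#'   arrays, or an integer array index.
#' @param expressed logical mask of expressed genes; computed with
#'   [expressed_mask()] when `NULL`.
#' @param threshold expression threshold used when `expressed` is `NULL`.
#' @param trim residual trimming constant in residual-SD units (default 3,
#'   the same constant as the background fit).
#' @param max_iter iteration cap per array.
#' @return list with `matrix` (adjusted [expr_matrix()]) and `adjustments`
#'   (per array: `slope`, `intercept`, `ee_mask`, `resid_sd`, `n_iterations`).
#' @export
robust_regression_adjust <- function(matrix, reference = "median",
                                     expressed = NULL, threshold = 3,
                                     trim = 3, max_iter = 100L) {
  validate_expr_matrix(matrix)
  if (is.null(expressed)) expressed <- expressed_mask(matrix, threshold)
  if (sum(expressed) < 30L) {
    stop("fewer than 30 expressed genes: cannot adjust profiles", call. = FALSE)
  }
  vals <- unclass(matrix)
  ref <- if (identical(reference, "median")) {
    apply(vals, 1L, stats::median)
  } else {
    vals[, as.integer(reference)]
  }
  adjustments <- vector("list", ncol(vals))
  out <- vals
  for (j in seq_len(ncol(vals))) {
    fit <- robust_line_fit(vals[, j], ref, expressed, trim = trim,
                           max_iter = max_iter)
    out[, j] <- (vals[, j] - fit$intercept) / fit$slope
    adjustments[[j]] <- fit
  }
  names(adjustments) <- colnames(vals)
  list(matrix = as_expr_matrix(out,
                               sorted_by_mean = isTRUE(attr(matrix, "sorted_by_mean"))),
       adjustments = adjustments)
}

#' Two-step internal-standard normalization
#'
#' Step one standardizes each array against its own fitted background
#' ([standardize()]); step two adjusts the standardized profiles onto the
#' gene-wise median profile by trimmed robust regression
#' ([robust_regression_adjust()]), with the expressed-gene mask recomputed
#' on the standardized data. Output is in background-SD units on a common
#' scale; values may legitimately be negative.
#'
#' @param matrix an [expr_matrix()] of raw intensities.
#' @param threshold expression threshold in background-SD units (default 3).
#' @param reference reference for step two (`"median"` or an array index).
#' @param detail if `TRUE` return the background models and per-array
#'   adjustments alongside the matrix.
#' @return the normalized [expr_matrix()]; with `detail = TRUE`, a list
#'   `(matrix, models, adjustments)`.
#' @export
two_step_normalize <- function(matrix, threshold = 3, reference = "median",
                               detail = FALSE) {
  step1 <- standardize(matrix)
  step2 <- robust_regression_adjust(step1$matrix, reference = reference,
                                    threshold = threshold)
  if (detail) {
    list(matrix = step2$matrix, models = step1$models,
         adjustments = step2$adjustments)
  } else {
    step2$matrix
  }
}

#' Quantile normalization (comparator)
#'
#' Standard rank-mean quantile normalization: after normalization every
#' array's sorted values equal the across-array mean of sorted values (ties
#' averaged). Backed by `limma::normalizeQuantiles`.
#'
#' @param matrix an [expr_matrix()].
#' @return the normalized [expr_matrix()].
#' @export
quantile_normalize <- function(matrix) {
  validate_expr_matrix(matrix)
  out <- limma::normalizeQuantiles(unclass(matrix), ties = TRUE)
  dimnames(out) <- dimnames(matrix)
  as_expr_matrix(out, sorted_by_mean = isTRUE(attr(matrix, "sorted_by_mean")))
}

#' Lowess MA-trend normalization (comparator)
#'
#' Removes, per array, the locally weighted regression trend of
#' `M = log2(array) - log2(reference)` on `A = (log2(array) + log2(reference)) / 2`
#' against the gene-wise median reference profile, then transforms back to
#' the intensity scale. A pseudo-count `offset` keeps zeros finite on the
#' log scale.
#'
#' @param matrix an [expr_matrix()] of non-negative intensities.
#' @param span lowess smoother span (default 0.3).
#' @param offset pseudo-count added before the log transform (default 1).
#' @return the normalized [expr_matrix()].
#' @export
lowess_normalize <- function(matrix, span = 0.3, offset = 1) {
  validate_expr_matrix(matrix)
  vals <- unclass(matrix)
  if (any(vals + offset <= 0)) {
    bad <- rownames(vals)[apply(vals + offset <= 0, 1L, any)]
    stop("values not positive after offset for genes: ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  lx <- log2(vals + offset)
  ref <- apply(lx, 1L, stats::median)
  out <- vals
  for (j in seq_len(ncol(vals))) {
    M <- lx[, j] - ref
    A <- (lx[, j] + ref) / 2
    fit <- stats::lowess(A, M, f = span)
    trend <- stats::approx(fit$x, fit$y, xout = A, rule = 2, ties = mean)$y
    out[, j] <- 2^(lx[, j] - trend) - offset
  }
  as_expr_matrix(out, sorted_by_mean = isTRUE(attr(matrix, "sorted_by_mean")))
}
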