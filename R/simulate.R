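#' Simulation settings for microarray-like expression data
#'
#' Describes a homogeneous single-channel array cohort: a background cohort
#' of non-expressed genes whose signal is pure additive normal noise, an
#' expressed cohort with lognormally spread abundances covering a wide
#' dynamic range, multiplicative per-gene biological noise (a small fraction
#' of genes hypervariable), and per-array linear distortions (multiplicative
#' scale and additive offset) that the normalization step is meant to remove.
#'
#' Intensity-scale defaults (`bg_mean` 100, `bg_sd` 15, median expressed
#' abundance 1000, lognormal sdlog 1.3) emulate a bead-array raw-intensity
#' scale: background around 100 units, detected genes spanning roughly
#' 20 to 50,000 units.
#'
#' @param n_genes number of genes (default 20000).
#' @param n_samples number of arrays (default 20).
#' @param frac_expressed fraction of genes in the expressed cohort (default 0.5).
#' @param bg_mean,bg_sd background noise mean and SD (intensity units).
#' @param expr_log_mean,expr_log_sd lognormal meanlog/sdlog of expressed-gene
#'   abundance (intensity units on the natural scale).
#' @param cv_bio per-gene biological coefficient of variation of expressed
#'   genes (default 0.1).
#' @param frac_hypervariable fraction of all genes with inflated variability
#'   (default 0.01), drawn from the expressed cohort, at coefficient of
#'   variation `cv_hyper`.
#' @param cv_hyper coefficient of variation of hypervariable genes (default 0.6).
#' @param array_scale_sd sdlog of the per-array multiplicative distortion.
#' @param array_offset_sd SD of the per-array additive offset (intensity units).
#' @param seed integer seed making the draw reproducible.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 20000L, n_samples = 20L,
                       frac_expressed = 0.5,
                       bg_mean = 100, bg_sd = 15,
                       expr_log_mean = log(1000), expr_log_sd = 1.3,
                       cv_bio = 0.1,
                       frac_hypervariable = 0.01, cv_hyper = 0.6,
                       array_scale_sd = 0.1, array_offset_sd = 10,
                       seed = 1L) {
  n_genes <- as.integer(n_genes)
  n_samples <- as.integer(n_samples)
  fracs <- c(frac_expressed = frac_expressed,
             frac_hypervariable = frac_hypervariable)
  if (any(fracs < 0 | fracs > 1)) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  if (n_genes < 2L || n_samples < 2L) {
    stop("need n_genes >= 2 and n_samples >= 2", call. = FALSE)
  }
  if (bg_sd <= 0) stop("bg_sd must be positive", call. = FALSE)
  if (expr_log_sd < 0 || cv_bio < 0 || cv_hyper < 0 ||
      array_scale_sd < 0 || array_offset_sd < 0) {
    stop("dispersion parameters must be non-negative", call. = FALSE)
  }
  structure(list(n_genes = n_genes, n_samples = n_samples,
                 frac_expressed = frac_expressed,
                 bg_mean = bg_mean, bg_sd = bg_sd,
                 expr_log_mean = expr_log_mean, expr_log_sd = expr_log_sd,
                 cv_bio = cv_bio, frac_hypervariable = frac_hypervariable,
                 cv_hyper = cv_hyper, array_scale_sd = array_scale_sd,
                 array_offset_sd = array_offset_sd, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a homogeneous microarray-like expression matrix
#'
#' Draws, for gene g and array s,
#' `value = scale_s * abundance_g * (1 + bio_noise_gs) + offset_s + bg_noise_gs`
#' where `abundance_g` is 0 for background genes and
#' `Lognormal(expr_log_mean, expr_log_sd)` for expressed genes,
#' `bio_noise ~ N(0, cv)` with the gene's coefficient of variation,
#' `bg_noise ~ N(bg_mean, bg_sd)`, `scale_s ~ Lognormal(0, array_scale_sd)`
#' and `offset_s ~ N(0, array_offset_sd)`. Negative values are clipped to 0
#' (the clipped fraction is attached as an attribute). All samples are
#' exchangeable: no gene carries a systematic group effect.
#'
#' @param config a [sim_config()].
#' @return an [expr_matrix()] with attributes `cohort` (per-gene label in
#'   `background`/`expressed`/`hypervariable`), `abundance` (per-gene true
#'   abundance) and `clipped_fraction`.
#' @export
simulate_matrix <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  G <- config$n_genes
  S <- config$n_samples
  set.seed(config$seed)

  n_expr <- round(config$frac_expressed * G)
  cohort <- rep("background", G)
  if (n_expr > 0L) {
    expr_idx <- seq_len(n_expr)       # cohort assignment; row order is arbitrary
    cohort[expr_idx] <- "expressed"
    # hypervariable fraction counts against all genes, drawn from the
    # expressed cohort (background genes have no signal to be variable in)
    n_hyper <- min(round(config$frac_hypervariable * G), n_expr)
    if (n_hyper > 0L) cohort[sample(expr_idx, n_hyper)] <- "hypervariable"
  }
  abundance <- numeric(G)
  is_expr <- cohort != "background"
  abundance[is_expr] <- stats::rlnorm(sum(is_expr), config$expr_log_mean,
                                      config$expr_log_sd)
  cv <- numeric(G)
  cv[cohort == "expressed"] <- config$cv_bio
  cv[cohort == "hypervariable"] <- config$cv_hyper

  scale_s <- stats::rlnorm(S, 0, config$array_scale_sd)
  offset_s <- stats::rnorm(S, 0, config$array_offset_sd)

  bio <- matrix(stats::rnorm(G * S), G, S) * cv
  signal <- (abundance * (1 + bio))
  values <- sweep(sweep(signal, 2L, scale_s, `*`), 2L, offset_s, `+`) +
    matrix(stats::rnorm(G * S, config$bg_mean, config$bg_sd), G, S)
  clipped <- mean(values < 0)
  values[values < 0] <- 0

  dimnames(values) <- list(sprintf("g%05d", seq_len(G)),
                           sprintf("s%02d", seq_len(S)))
  out <- expr_matrix(values)
  attr(out, "cohort") <- cohort
  attr(out, "abundance") <- abundance
  attr(out, "clipped_fraction") <- clipped
  out
}

#' Simulate a homogeneous group of samples
#'
#' As [simulate_matrix()] but returning only the matrix: by construction all
#' samples are exchangeable draws from the same per-gene distribution, so an
#' arbitrary split into two subgroups carries no systematic difference --
#' the premise of the benchmark's control/experimental split.
#'
#' @param config a [sim_config()].
#' @return an [expr_matrix()] without cohort metadata.
#' @export
simulate_homogeneous_group <- function(config = sim_config()) {
  out <- simulate_matrix(config)
  attr(out, "cohort") <- NULL
  attr(out, "abundance") <- NULL
  out
}
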