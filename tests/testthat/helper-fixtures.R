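# Shared fixtures, memoized so expensive simulations are drawn once per run.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# paper-scale homogeneous cohort (20,000 x 20), used by the acceptance tests
full_cohort <- function() {
  cached("full_cohort", simulate_homogeneous_group(sim_config(seed = 101L)))
}

# small cohort for fast module tests
small_cohort <- function(n_genes = 4000L, n_samples = 12L, seed = 7L) {
  cached(sprintf("small_%d_%d_%d", n_genes, n_samples, seed),
         simulate_homogeneous_group(
           sim_config(n_genes = n_genes, n_samples = n_samples, seed = seed)))
}

# literal tiny matrix with known values
tiny_matrix <- function() {
  expr_matrix(matrix(1:6, nrow = 3, byrow = TRUE,
                     dimnames = list(c("g1", "g2", "g3"), c("s1", "s2"))) * 1.0)
}

# a mean-sorted matrix with smoothly decreasing rows, for injection tests
sorted_fixture <- function(G = 20000L, S = 4L, seed = 3L) {
  cached(sprintf("sorted_%d_%d_%d", G, S, seed), {
    set.seed(seed)
    vals <- matrix(rep(seq(G, 1) * 10, S), nrow = G) +
      matrix(runif(G * S), G, S)
    dimnames(vals) <- list(sprintf("g%05d", seq_len(G)),
                           sprintf("s%02d", seq_len(S)))
    sort_by_mean(expr_matrix(vals))
  })
}

# run one normalization + DE pass on a benchmark, as the evaluators do
run_null_analysis <- function(matrix_sorted, split_seed,
                              restrictions = analysis_restrictions()) {
  halves <- split_group(matrix_sorted, permutation_seed = split_seed)
  S2 <- ncol(halves$control)
  pooled <- expr_matrix(cbind(unclass(halves$control),
                              unclass(halves$experimental)))
  norm <- two_step_normalize(pooled)
  ctrl <- expr_matrix(unclass(norm)[, seq_len(S2)])
  expe <- expr_matrix(unclass(norm)[, S2 + seq_len(S2)])
  associative_analysis(ctrl, expe, restrictions)
}
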