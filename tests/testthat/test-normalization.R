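test_that("background fit recovers a contaminated normal cohort", {
  set.seed(21)
  vals <- c(rnorm(10000, 100, 15), runif(10000, 400, 40000))
  bg <- fit_background(vals)
  expect_true(bg$converged)
  expect_lt(abs(bg$Av - 100) / 100, 0.02)
  expect_lt(abs(bg$SD - 15) / 15, 0.05)
  # the expressed cohort is excluded from membership
  expect_true(all(which(bg$member_mask) <= 10000))
})

test_that("background fit is de-biased on a pure normal sample", {
  set.seed(22)
  bg <- fit_background(rnorm(10000))
  se <- 1 / sqrt(10000)
  expect_lt(abs(bg$Av), 3 * se)
  expect_lt(abs(bg$SD - 1), 0.05)
})

test_that("degenerate backgrounds are rejected", {
  expect_error(fit_background(rep(5, 1000)), "zero spread")
  expect_error(fit_background(rnorm(100)), "at least 200")
})

test_that("standardization maps the background to mean 0, SD 1", {
  cfg <- sim_config(n_genes = 10000, n_samples = 4, seed = 23)
  m <- simulate_matrix(cfg)
  std <- standardize(m)
  for (j in seq_len(ncol(m))) {
    refit <- fit_background(unclass(std$matrix)[, j])
    expect_lt(abs(refit$Av), 0.05)
    expect_lt(abs(refit$SD - 1), 0.05)
  }
  # the threshold point: a raw value Av + 3 SD becomes 3.0 exactly
  b <- std$models[[1]]
  expect_equal((b$Av + 3 * b$SD - b$Av) / b$SD, 3.0)
})

test_that("expressed_mask applies the 3-SD mean criterion", {
  vals <- matrix(c(rep(2.9, 4), rep(3.01, 4)), nrow = 2, byrow = TRUE,
                 dimnames = list(c("low", "high"), sprintf("s%d", 1:4)))
  expect_equal(unname(expressed_mask(expr_matrix(vals))), c(FALSE, TRUE))

  cfg <- sim_config(n_genes = 10000, n_samples = 6, seed = 24)
  std <- standardize(simulate_matrix(cfg))$matrix
  expect_lt(abs(mean(expressed_mask(std)) - cfg$frac_expressed), 0.05)
})

test_that("robust regression recovers exact and contaminated linear maps", {
  set.seed(25)
  a <- runif(2000, 4, 200)
  exact <- expr_matrix(matrix(c(a, 2 * a + 1), ncol = 2,
                              dimnames = list(sprintf("g%04d", 1:2000),
                                              c("A", "B"))))
  adj <- robust_regression_adjust(exact, reference = 1L)
  expect_equal(adj$adjustments$B$slope, 2, tolerance = 1e-6)
  expect_equal(adj$adjustments$B$intercept, 1, tolerance = 1e-6)
  expect_equal(unclass(adj$matrix)[, "B"], unclass(exact)[, "A"],
               tolerance = 1e-9)
  # reference = the array itself: identity map
  expect_equal(adj$adjustments$A$slope, 1, tolerance = 1e-12)
  expect_equal(adj$adjustments$A$intercept, 0, tolerance = 1e-9)

  # 5% gross contamination: displaced genes leave the ee set
  b <- 2 * a + 1 + rnorm(2000, 0, 0.5)
  hit <- sample(2000, 100)
  b[hit] <- b[hit] + 10 * 0.5
  cont <- expr_matrix(matrix(c(a, b), ncol = 2,
                             dimnames = list(sprintf("g%04d", 1:2000),
                                             c("A", "B"))))
  adj2 <- robust_regression_adjust(cont, reference = 1L)
  expect_lt(abs(adj2$adjustments$B$slope - 2) / 2, 0.01)
  expect_lt(abs(adj2$adjustments$B$intercept - 1), 0.2)
  expect_true(all(!adj2$adjustments$B$ee_mask[hit]))
})

test_that("robust regression rejects pathological arrays", {
  set.seed(26)
  a <- runif(500, 4, 100)
  anti <- expr_matrix(matrix(c(a, 200 - a), ncol = 2,
                             dimnames = list(sprintf("g%03d", 1:500),
                                             c("A", "B"))))
  expect_error(robust_regression_adjust(anti, reference = 1L),
               "anti-correlated")
  few <- expr_matrix(matrix(runif(40, 0, 1), 20, 2,
                            dimnames = list(sprintf("g%02d", 1:20),
                                            c("a", "b"))))
  expect_error(robust_regression_adjust(few, reference = 1L),
               "fewer than 30 expressed genes")
})

test_that("two-step normalization preserves within-array gene ranking", {
  m <- simulate_matrix(sim_config(n_genes = 5000, n_samples = 6, seed = 27))
  norm <- two_step_normalize(m)
  for (j in seq_len(ncol(m))) {
    expect_identical(order(unclass(norm)[, j]), order(unclass(m)[, j]))
  }
})

test_that("quantile normalization equalizes the column distributions", {
  m <- expr_matrix(matrix(c(1, 2, 3, 4, 5, 6), nrow = 3,
                          dimnames = list(c("g1", "g2", "g3"), c("a", "b"))))
  q <- quantile_normalize(m)
  expect_equal(unname(unclass(q)[, 1]), c(2.5, 3.5, 4.5))
  expect_equal(unname(unclass(q)[, 2]), c(2.5, 3.5, 4.5))

  same <- expr_matrix(matrix(rep(c(5, 1, 3), 2), nrow = 3,
                             dimnames = list(c("g1", "g2", "g3"),
                                             c("a", "b"))))
  expect_equal(unclass(quantile_normalize(same)), unclass(same),
               ignore_attr = TRUE)

  set.seed(28)
  r <- expr_matrix(matrix(rlnorm(400 * 5, 4, 1), 400, 5,
                          dimnames = list(sprintf("g%03d", 1:400),
                                          sprintf("s%d", 1:5))))
  qn <- unclass(quantile_normalize(r))
  sorted_cols <- apply(qn, 2, sort)
  expect_true(all(abs(sorted_cols - sorted_cols[, 1]) < 1e-9))
})

test_that("lowess normalization is the identity on trend-free arrays", {
  set.seed(29)
  ref <- rlnorm(1000, 5, 1.5)
  m <- expr_matrix(matrix(rep(ref, 3), ncol = 3,
                          dimnames = list(sprintf("g%04d", 1:1000),
                                          c("a", "b", "c"))))
  out <- lowess_normalize(m)
  expect_equal(unclass(out), unclass(m), tolerance = 1e-9, ignore_attr = TRUE)

  # constant multiplicative distortion is removed on the interior range
  m2 <- expr_matrix(matrix(c(ref, ref, 1.6 * ref), ncol = 3,
                           dimnames = list(sprintf("g%04d", 1:1000),
                                           c("a", "b", "c"))))
  out2 <- unclass(lowess_normalize(m2))
  interior <- ref > quantile(ref, 0.1) & ref < quantile(ref, 0.9)
  expect_lt(max(abs(out2[interior, "c"] - ref[interior]) / ref[interior]), 0.05)
})

test_that("lowess shrinks one-directional injected fold changes", {
  m <- small_cohort(n_genes = 5000, n_samples = 8, seed = 30)
  bench <- make_benchmark(m, injection_design(Fd = 2, fraction = 0.10,
                                              mode = "asymmetric_up"),
                          permutation_seed = 1)
  pooled <- expr_matrix(cbind(unclass(bench$control),
                              unclass(bench$experimental)))
  norm <- unclass(lowess_normalize(pooled))
  up <- bench$truth$label == "up" & rowMeans(unclass(bench$control)) > 500
  rec_fold <- rowMeans(norm[up, 5:8]) / rowMeans(norm[up, 1:4])
  expect_lt(mean(rec_fold), 2)  # the trend removal eats part of the change
})

test_that("the normalizer registry lists built-ins and rejects duplicates", {
  expect_true(all(c("two_step", "quantile", "lowess") %in% list_normalizers()))
  name <- paste0("test_norm_", sample.int(1e6, 1))
  register_normalizer(name, function(m) m)
  expect_true(name %in% list_normalizers())
  expect_error(register_normalizer(name, function(m) m), "already registered")
  expect_error(debench:::get_normalizer("no_such_method"), "unknown normalizer")
  debench:::reset_registries()
})
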