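norm_matrix <- function(vals, prefix = "s") {
  dimnames(vals) <- list(sprintf("g%05d", seq_len(nrow(vals))),
                         sprintf("%s%02d", prefix, seq_len(ncol(vals))))
  expr_matrix(vals)
}

test_that("reference group admits ~(1 - alpha_F) of equal-variance genes", {
  set.seed(31)
  G <- 4000; n <- 10
  ctrl <- norm_matrix(matrix(rnorm(G * n, 10, 1), G, n))
  ref <- select_reference_group(ctrl, expressed = rep(TRUE, G), alpha_F = 0.05)
  frac <- length(ref$gene_ids) / G
  expect_lt(abs(frac - 0.95), 0.03)
  # pooled residual bookkeeping: members x replicates
  expect_length(ref$pooled_residuals, length(ref$gene_ids) * n)
  expect_lt(abs(ref$resid_sd - 1), 0.05)
})

test_that("high-variance genes are excluded from the reference", {
  set.seed(32)
  G <- 1000; n <- 8
  vals <- matrix(rnorm(G * n, 10, 1), G, n)
  vals[1, ] <- rnorm(n, 10, 10)  # 100x variance
  ctrl <- norm_matrix(vals)
  ref <- select_reference_group(ctrl, expressed = rep(TRUE, G))
  expect_false(rownames(ctrl)[1] %in% ref$gene_ids)
})

test_that("a too-small reference is rejected with advice", {
  set.seed(33)
  ctrl <- norm_matrix(matrix(rnorm(2000 * 6, 10, 1), 2000, 6))
  expect_error(select_reference_group(ctrl, expressed = rep(TRUE, 2000),
                                      floor = 1950),
               "larger alpha_F")
  expect_error(select_reference_group(ctrl, expressed = rep(FALSE, 2000)),
               "expressed genes")
})

test_that("student filter matches the closed-form t-test", {
  ctrl <- c(10, 12, 11, 13, 9)
  expe <- c(20, 22, 21, 23, 19)
  res <- student_filter(ctrl, expe)
  oracle <- t.test(expe, ctrl, var.equal = TRUE)
  expect_equal(res$p_value, oracle$p.value, tolerance = 1e-10)
  expect_true(res$pass)

  same <- student_filter(c(1, 2, 3), c(1, 2, 3))
  expect_gt(same$p_value, 0.9)
  expect_false(same$pass)

  flat <- student_filter(c(0, 0, 0, 0, 0), c(5, 5, 5, 5, 5))
  expect_equal(flat$p_value, 0)  # zero pooled variance, unequal means
  expect_true(flat$pass)
  expect_equal(student_filter(rep(2, 4), rep(2, 4))$p_value, 1)
  expect_error(student_filter(1, c(1, 2)), "at least 2 replicates")
})

test_that("associative test equals the two-sample t closed form", {
  set.seed(34)
  pool <- rnorm(500)
  ref <- structure(list(gene_ids = sprintf("r%03d", 1:50),
                        pooled_residuals = pool,
                        resid_sd = sd(pool), tech_var = 1, n_samples = 10),
                   class = "reference_group")
  x <- rnorm(5, 1, 1)
  expect_equal(associative_test(x, ref),
               t.test(x, pool, var.equal = TRUE)$p.value, tolerance = 1e-10)

  sym <- structure(list(gene_ids = "r", pooled_residuals = rep(c(-1, 1), 200),
                        resid_sd = 1, tech_var = 1, n_samples = 10),
                   class = "reference_group")
  expect_equal(associative_test(rep(0, 4), sym), 1)

  far <- rep(10 * sd(pool), 10)
  expect_lt(associative_test(far, ref), 1e-15)
  expect_error(associative_test(1, ref), "at least 2 residuals")
})

test_that("restrictions gate selection and record reasons", {
  base <- data.frame(gene_id = c("a", "b", "c"),
                     mean_control = c(30, 19.9, 30),
                     mean_experimental = c(42, 19.9, 80),
                     fold = c(1.4, 1.0, 2.7),
                     p_student = c(1e-4, 1e-4, 1e-4),
                     p_assoc = c(1e-9, 1e-9, 1e-9))
  out <- apply_restrictions(base, analysis_restrictions(Fa = 1.5, Em = 20),
                            n_genes_tested = 100)
  expect_equal(out$selected, c(FALSE, FALSE, TRUE))
  expect_match(out$reasons_rejected[1], "fold")
  expect_match(out$reasons_rejected[2], "fold,expression")
  expect_equal(out$direction, c("none", "none", "up"))
})

test_that("a null associative run yields at most a handful of selections", {
  m <- small_cohort(n_genes = 8000, n_samples = 12, seed = 35)
  res <- run_null_analysis(sort_by_mean(m), split_seed = 1)
  expect_lte(sum(res$selected), 10)
})

test_that("selected genes always satisfy the fold and expression gates", {
  m <- small_cohort(n_genes = 6000, n_samples = 12, seed = 36)
  bench <- make_benchmark(m, injection_design(), permutation_seed = 2)
  pooled <- expr_matrix(cbind(unclass(bench$control),
                              unclass(bench$experimental)))
  norm <- two_step_normalize(pooled)
  ctrl <- expr_matrix(unclass(norm)[, 1:6])
  expe <- expr_matrix(unclass(norm)[, 7:12])
  restr <- analysis_restrictions()
  res <- associative_analysis(ctrl, expe, restr)
  sel <- res[res$selected, ]
  expect_gt(nrow(sel), 0)
  expect_true(all(sel$fold >= restr$Fa))
  expect_true(all(pmax(sel$mean_control, sel$mean_experimental) >= restr$Em))
  expect_true(all(sel$p_student < restr$alpha_student))
  expect_true(all(sel$p_assoc < restr$alpha_assoc / nrow(res)))
  expect_true(all(sel$direction %in% c("up", "down")))
})

test_that("sensitivity is non-decreasing in the injected fold change", {
  m <- small_cohort(n_genes = 6000, n_samples = 12, seed = 37)
  sens <- vapply(c(1.5, 2, 4), function(fd) {
    ev <- evaluate_repeats(m, injection_design(Fd = fd), n_repeats = 3,
                           base_seed = 9)
    ev$overall$mean[ev$overall$metric == "sensitivity"]
  }, numeric(1))
  expect_true(all(diff(sens) > -0.02))  # monotone up to Monte-Carlo noise
  expect_gt(sens[3], sens[1])
})

test_that("hypervariable flagging is calibrated and improves sensitivity", {
  set.seed(38)
  G <- 2000; n <- 6
  ctrl <- norm_matrix(matrix(rnorm(G * n, 30, 2), G, n))
  expe <- norm_matrix(matrix(rnorm(G * n, 30, 2), G, n), prefix = "e")
  flags <- exclude_hypervariable(ctrl, expe, alpha_F = 0.05)
  expect_lt(abs(mean(flags) - 0.05), 0.03)  # null calibration

  vals <- unclass(ctrl); vals[1, ] <- rnorm(n, 30, 20)  # 10x typical CV
  noisy <- norm_matrix(vals)
  expect_true(exclude_hypervariable(noisy, expe, alpha_F = 0.05)[1])

  # benchmark salted with hypervariable modified genes: exclusion lifts
  # sensitivity computed on the remaining genes
  set.seed(39)
  hyper <- seq_len(200)
  ctrl_v <- matrix(rnorm(G * n, 50, 2), G, n)
  expe_v <- matrix(rnorm(G * n, 50, 2), G, n)
  ctrl_v[hyper, ] <- rnorm(200 * n, 50, 25)
  expe_v[hyper, ] <- rnorm(200 * n, 50, 25)
  modified <- seq(1, G, by = 5)  # includes 40 hypervariable genes
  expe_v[modified, ] <- expe_v[modified, ] * 2
  ctrl_m <- norm_matrix(ctrl_v)
  expe_m <- norm_matrix(expe_v, prefix = "e")
  truth <- truth_table(rownames(ctrl_m),
                       ifelse(seq_len(G) %in% modified, "up", "unchanged"),
                       ifelse(seq_len(G) %in% modified, 2, 1))
  flags2 <- exclude_hypervariable(ctrl_m, expe_m)
  plain <- associative_analysis(ctrl_m, expe_m)
  excl <- associative_analysis(ctrl_m, expe_m, exclude = flags2)
  sens_plain <- classification_metrics(confusion(plain, truth))["sensitivity"]
  sens_excl <- classification_metrics(
    confusion(excl, truth, eligible = !flags2))["sensitivity"]
  expect_gt(sens_excl, sens_plain)
})

test_that("the Welch/BH baseline is calibrated and matches its oracle", {
  set.seed(40)
  G <- 1000; n <- 6
  ctrl <- norm_matrix(matrix(rnorm(G * n, 30, 3), G, n))
  expe <- norm_matrix(matrix(rnorm(G * n, 30, 3), G, n), prefix = "e")
  null_res <- ttest_bh_baseline(ctrl, expe)
  expect_lte(sum(null_res$selected), 1)
  expect_equal(null_res$p_value[1],
               t.test(unclass(expe)[1, ], unclass(ctrl)[1, ])$p.value,
               tolerance = 1e-10)

  vals <- unclass(expe); vals[1:50, ] <- vals[1:50, ] + 30
  shifted <- norm_matrix(vals, prefix = "e")
  res <- ttest_bh_baseline(ctrl, shifted)
  expect_true(all(res$selected[1:50]))
  expect_lte(sum(res$selected[-(1:50)]), 2)
})

test_that("the DE registry hosts external gene lists", {
  expect_true(all(c("associative", "ttest_bh") %in% list_de_methods()))
  path <- withr::local_tempfile(fileext = ".tsv")
  m <- small_cohort(n_genes = 4000, n_samples = 12, seed = 7)
  ids <- rownames(m)
  writeLines(c("gene_id\tselected",
               paste(ids[1:5], "1", sep = "\t")), path)
  name <- paste0("external_", sample.int(1e6, 1))
  register_de_method(name, function(control, experimental, restrictions) {
    listed <- utils::read.delim(path)$gene_id
    data.frame(gene_id = rownames(control),
               selected = rownames(control) %in% listed,
               direction = ifelse(rownames(control) %in% listed, "up", "none"))
  })
  expect_error(register_de_method(name, function(...) NULL),
               "already registered")
  fn <- debench:::get_de_method(name)
  out <- fn(m, m, analysis_restrictions())
  expect_equal(sum(out$selected), 5)
  debench:::reset_registries()
})
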