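test_that("pearson correlation handles exact, degenerate and invariant cases", {
  r <- pearson_cor(c(1, 2, 3), c(2, 4, 6))
  expect_equal(r$r, 1)
  expect_equal(r$n, 3L)
  expect_error(pearson_cor(1:5, rep(2, 5)), "degenerate")
  expect_error(pearson_cor(1:4, 1:5), "lengths")

  set.seed(6)
  x <- rnorm(40); y <- rnorm(40) + 0.5 * x
  base <- pearson_cor(x, y)
  perm <- sample.int(40)
  expect_equal(pearson_cor(x[perm], y[perm])$r, base$r)
  # affine invariance, sign flip under negative scale
  expect_equal(pearson_cor(3 * x + 7, y)$r, base$r)
  expect_equal(pearson_cor(-2 * x + 1, y)$r, -base$r)
  # p-value equals the textbook t transform
  tt <- base$r * sqrt((40 - 2) / (1 - base$r^2))
  expect_equal(base$p_two_tailed, 2 * pt(-abs(tt), 38))
})

test_that("a correlation of 0.898 explains 80.6 percent of variance", {
  d <- make_exact_r(0.898, n = 8)
  res <- pearson_cor(d$x, d$y)
  expect_equal(res$r, 0.898, tolerance = 1e-10)
  expect_equal(round(res$r_squared, 3), 0.806)
})

test_that("simple regression matches least squares and the r-squared identity", {
  x <- c(0, 1, 2, 3, 4)
  # lm warns about the numerically perfect fit; the point is the algebra
  fit <- suppressWarnings(linear_regression(x, 3 * x + 1))
  expect_equal(fit$slope, 3)
  expect_equal(fit$intercept, 1)
  expect_equal(fit$r_squared, 1)
  expect_error(linear_regression(x, rep(2, 5)), "degenerate")

  set.seed(8)
  for (i in 1:5) {
    x <- rnorm(25); y <- rnorm(25, 2 - x)
    expect_lt(abs(linear_regression(x, y)$r_squared - pearson_cor(x, y)$r^2),
              1e-12)
  }
})

test_that("pooled-variance t-test matches Student's formulation and a permutation oracle", {
  same <- c(1, 2, 3, 4)
  r0 <- two_sample_t(same, same)
  expect_equal(r0$t, 0)
  expect_equal(r0$p_two_tailed, 1)
  expect_equal(r0$df, 6L)
  far <- two_sample_t(c(1, 2, 3), c(1, 2, 3) + 100)
  expect_lt(far$p_two_tailed, 0.001)
  expect_error(two_sample_t(1, c(1, 2)), "n >= 2")

  # designed 4-vs-4 fixtures: the exhaustive permutation distribution has
  # resolution 1/70, so the comparison is meaningful where the reference
  # stats bracket the observed difference smoothly
  fixtures <- list(
    list(a = c(1.0, 2.1, 3.0, 4.2), b = c(3.4, 4.6, 5.5, 6.4)),
    list(a = c(10.1, 11.9, 13.2, 14.8), b = c(12.6, 14.4, 15.7, 17.3)),
    list(a = c(1, 2, 3, 4), b = c(2.6, 3.6, 4.6, 5.6)))
  for (fx in fixtures) {
    got <- two_sample_t(fx$a, fx$b)$p_two_tailed
    expect_lt(abs(got - oracle_permutation_p(fx$a, fx$b)), 0.02)
  }
})

test_that("sample size calculation reproduces the study's group size", {
  # difference 30, sd 15, power 80%, alpha 5% -> 4 per group
  expect_identical(sample_size_normal(30, 15, 0.80, 0.05), 4L)
  # classic rule-of-thumb: delta = sd needs 16 per group
  expect_identical(sample_size_normal(15, 15, 0.80, 0.05), 16L)
  expect_error(sample_size_normal(30, 15, power = 1), "power")
  expect_error(sample_size_normal(-1, 15), "delta")
  # monotone in effect size and power
  n_small <- sample_size_normal(10, 15)
  n_big <- sample_size_normal(20, 15)
  expect_lte(n_big, n_small)
  expect_gte(sample_size_normal(10, 15, power = 0.95),
             sample_size_normal(10, 15, power = 0.80))
  # the exact noncentral-t route is never smaller
  expect_gte(sample_size_normal(30, 15, method = "exact"),
             sample_size_normal(30, 15))
})

test_that("correlation tables flag significance consistently", {
  co <- generate_cohort(cohort_spec(n_subjects = 40, rng_seed = 3))
  pairs <- list(c("age", "MD"), c("age", "IMAT_pct"), c("MD", "IMAT_pct"),
                c("IMAT_pct", "rise_time"))
  tab <- correlation_table(co, pairs)
  expect_equal(nrow(tab), length(pairs))
  for (i in seq_len(nrow(tab))) {
    ref <- pearson_cor(co[[tab$var1[i]]], co[[tab$var2[i]]])
    expect_equal(tab$r[i], ref$r)
    want <- if (ref$p_two_tailed < 0.01) "**" else
      if (ref$p_two_tailed < 0.05) "*" else ""
    expect_identical(tab$stars[i], want)
  }
  expect_error(correlation_table(co, list(c("age", "nope"))), "unknown")

  # noise-free cohort: every requested correlation is perfect
  co0 <- generate_cohort(cohort_spec(n_subjects = 20, imat_intercept = 50,
                                     noise_sds = list(md = 0, imat = 0, mv = 0,
                                                      rise = 0, strength = 0)))
  tab0 <- correlation_table(co0, pairs)
  expect_true(all(abs(abs(tab0$r) - 1) < 1e-12))
})
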