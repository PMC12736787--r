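test_that("group summaries use linear-interpolation quartiles and strict negativity", {
  s <- gravy_summary(c(1, 2, 3, 4, 5))
  expect_equal(s$median, 3)
  expect_equal(s$q1, 2)
  expect_equal(s$q3, 4)
  expect_equal(gravy_summary(c(-1, 1))$frac_negative, 0.5)
  expect_equal(gravy_summary(c(0, 1))$frac_negative, 0)  # strict < 0
  expect_error(gravy_summary(numeric(0)), "empty")
})

test_that("summary median of a large normal sample sits near its theoretical value", {
  withr::local_seed(123)
  x <- rnorm(10000, mean = -0.18, sd = 0.3)
  s <- gravy_summary(x)
  se_median <- 1.2533 * 0.3 / sqrt(10000)
  expect_lt(abs(s$median - (-0.18)), 3 * se_median)
  expect_equal(s$q1, unname(quantile(x, 0.25)))
})

test_that("Welch test matches the closed-form formula and handles identity", {
  res <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)

  x <- c(1, 2, 3, 4); y <- c(10, 11, 12, 13)
  res <- welch_t_test(x, y)
  oracle <- welch_formula(x, y)
  expect_equal(res$t, oracle$t, tolerance = 1e-12)
  expect_equal(res$df, oracle$df, tolerance = 1e-12)
  expect_equal(res$p, oracle$p, tolerance = 1e-12)
  expect_lt(res$p, 0.001)

  withr::local_seed(14)
  for (i in 1:20) {
    a <- rnorm(sample(3:40, 1)); b <- rnorm(sample(3:40, 1), sd = runif(1, 0.2, 3))
    got <- welch_t_test(a, b)
    want <- welch_formula(a, b)
    expect_equal(got$t, want$t, tolerance = 1e-10)
    expect_equal(got$df, want$df, tolerance = 1e-10)
    expect_equal(got$p, want$p, tolerance = 1e-10)
  }
})

test_that("Welch test is symmetric and rejects degenerate inputs", {
  x <- c(1.2, 3.4, 2.2, 5.1); y <- c(0.3, 0.9, 1.1)
  a <- welch_t_test(x, y); b <- welch_t_test(y, x)
  expect_equal(a$t, -b$t)
  expect_equal(a$p, b$p)
  expect_error(welch_t_test(1, c(1, 2)), "at least 2")
  expect_equal(welch_t_test(c(2, 2, 2), c(2, 2, 2))$p, 1)
  expect_error(welch_t_test(c(2, 2), c(3, 3)), "constant")
})

test_that("Mann-Whitney exact p matches full enumeration for small tie-free samples", {
  res <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(res$U, 0)
  expect_equal(res$p, 1 / 3, tolerance = 1e-12)

  withr::local_seed(15)
  for (i in 1:30) {
    nx <- sample(2:8, 1); ny <- sample(2:12, 1)
    pool <- sample(seq_len(200), nx + ny)  # distinct values: tie-free
    x <- pool[seq_len(nx)]; y <- pool[-seq_len(nx)]
    if (min(nx, ny) > 8) next
    expect_equal(mann_whitney_u(x, y)$p, mwu_enumeration_p(x, y), tolerance = 1e-9)
  }
})

test_that("identical multisets give a Mann-Whitney p near 1", {
  x <- c(1.5, 2.5, 2.5, 7)
  expect_gte(mann_whitney_u(x, x)$p, 0.99)
})

test_that("normal approximation stays within 0.02 of the exact p at min(n) = 8", {
  withr::local_seed(16)
  for (i in 1:10) {
    pool <- sample(seq_len(500), 8 + 12)
    x <- pool[1:8]; y <- pool[-(1:8)]
    p_exact <- mann_whitney_u(x, y)$p
    p_approx <- mann_whitney_u(x, y, exact_max = 0L)$p
    expect_lt(abs(p_exact - p_approx), 0.02)
  }
})

test_that("group comparison carries both tests and both summaries", {
  withr::local_seed(17)
  x <- rnorm(50, -0.25, 0.3); y <- rnorm(500, -0.18, 0.3)
  cmp <- compare_gravy_groups(x, y, label = "surface vs background")
  expect_s3_class(cmp, "gravy_comparison")
  expect_equal(cmp$summary_x$n, 50)
  expect_equal(cmp$welch_p, welch_t_test(x, y)$p)
  expect_equal(cmp$mwu_p, mann_whitney_u(x, y)$p)
  td <- tidy(cmp)
  expect_equal(nrow(td), 1)
  expect_equal(td$median_x, median(x))
  expect_error(compare_gravy_groups(1, y), "fewer than 2")
})

test_that("the surface profile report produces the three comparisons", {
  lab <- generate_proteome(
    proteome_spec(n_proteins = 500, n_secreted = 40, n_lipoprotein = 2,
                  n_lpxtg = 2, seed = 19)
  )
  prof <- run_profile(lab$proteome)
  expect_named(
    unclass(prof$comparisons),
    c("surface_vs_proteome", "surface_vs_background", "mature_vs_full")
  )
  td <- tidy(prof$comparisons)
  expect_equal(nrow(td), 3)
  expect_true(all(td$welch_p > 0 & td$welch_p <= 1))
  expect_true(all(td$mwu_p > 0 & td$mwu_p <= 1))
  # comparison (c) pairs equal-sized value sets from the same secreted proteins
  expect_equal(td$n_x[3], td$n_y[3])

  few <- tibble::tibble(gravy_full = rnorm(10), category = "none")
  expect_error(surface_profile_report(few), "surface")
})

test_that("whole-proteome hydrophilic fraction is the weighted mean of its parts", {
  withr::local_seed(20)
  rec <- tibble::tibble(
    gravy_full = rnorm(400, -0.1, 0.4),
    category = sample(c("secreted", "none"), 400, replace = TRUE, prob = c(0.1, 0.9))
  )
  surf <- rec$gravy_full[rec$category == "secreted"]
  bg <- rec$gravy_full[rec$category == "none"]
  whole <- gravy_summary(rec$gravy_full)$frac_negative
  weighted <- (length(surf) * gravy_summary(surf)$frac_negative +
               length(bg) * gravy_summary(bg)$frac_negative) / nrow(rec)
  expect_equal(whole, weighted, tolerance = 1e-12)
})
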