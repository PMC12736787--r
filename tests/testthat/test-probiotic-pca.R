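test_that("retention fractions convert log drops to surviving fractions", {
  expect_equal(retention_fraction(8.5, 8.5), 1)
  expect_equal(retention_fraction(8.5, 7.5), 0.1)
  expect_equal(retention_fraction(8, 8 - 0.30103), 0.5, tolerance = 1e-5)
  expect_error(retention_fraction(Inf, 8), "finite")
})

test_that("the feature matrix has one row per isolate and fixed column order", {
  panel <- generate_stress_panel(n_isolates = 3, dominant = "M2", seed = 41)
  fm <- build_feature_matrix(panel)
  expect_equal(dim(fm), c(3, 5))
  expect_equal(
    names(fm),
    c("isolate_id", "antagonism", "acid_retention", "bile_retention", "lysozyme_retention")
  )
  expect_true(all(fm$acid_retention > 0))

  incomplete <- panel[!(panel$isolate_id == "M1" & panel$stressor == "bile"), ]
  expect_error(build_feature_matrix(incomplete), "isolate M1: bile")
  expect_error(build_feature_matrix(panel[panel$isolate_id == "M1", ]), ">= 2 isolates")
})

test_that("z-scores hit mean 0 and unit SD under the population convention", {
  m <- tibble::tibble(isolate_id = c("a", "b", "c"), v = c(1, 2, 3))
  z <- zscore_columns(m)
  expect_equal(z$v, c(-1.2247449, 0, 1.2247449), tolerance = 1e-6)
  expect_equal(zscore_columns(z)$v, z$v, tolerance = 1e-12)  # idempotent

  zs <- zscore_columns(tibble::tibble(a = rnorm(10, 5, 2), b = runif(10)))
  for (col in c("a", "b")) {
    expect_lt(abs(mean(zs[[col]])), 1e-12)
    expect_equal(sqrt(sum(zs[[col]]^2) / 10), 1, tolerance = 1e-12)
  }

  expect_error(zscore_columns(tibble::tibble(v = rep(2, 4))), "constant")

  zsamp <- zscore_columns(m, sd_type = "sample")
  expect_equal(zsamp$v, c(-1, 0, 1))
})

test_that("PCA reconstructs the centered matrix with orthonormal loadings", {
  withr::local_seed(43)
  m <- tibble::tibble(
    isolate_id = paste0("iso", 1:10),
    a = rnorm(10), b = rnorm(10), c = rnorm(10), d = rnorm(10)
  )
  z <- zscore_columns(m)
  fit <- stress_pca(z)
  L <- as.matrix(fit$loadings[, -1])
  expect_equal(t(L) %*% L, diag(4), tolerance = 1e-9, ignore_attr = TRUE)
  S <- as.matrix(fit$scores[, -1])
  X <- as.matrix(z[, -1])
  Xc <- sweep(X, 2, colMeans(X))
  expect_lt(max(abs(S %*% t(L) - Xc)), 1e-9)
  # deterministic orientation: dominant loading of each component positive
  for (k in seq_len(ncol(L))) expect_gt(L[which.max(abs(L[, k])), k], 0)
})

test_that("explained-variance ratios are sorted, nonnegative, and sum to 1", {
  withr::local_seed(44)
  z <- zscore_columns(tibble::tibble(a = rnorm(8), b = rnorm(8), c = rnorm(8), d = rnorm(8)))
  r <- stress_pca(z)$explained_variance_ratio
  expect_true(all(diff(r) <= 1e-12))
  expect_true(all(r >= 0))
  expect_equal(sum(r), 1, tolerance = 1e-9)
})

test_that("component count is bounded by min(n_isolates - 1, n_variables)", {
  panel <- generate_stress_panel(n_isolates = 3, dominant = "M2", seed = 45)
  fit <- stress_pca(zscore_columns(build_feature_matrix(panel)))
  expect_lte(sum(fit$explained_variance_ratio > 0), 2)
})

test_that("a rank-1 pattern loads entirely on PC1", {
  base <- c(-1, 0, 2, 4)
  m <- tibble::tibble(a = base, b = 2 * base, c = -base, d = 0.5 * base)
  fit <- stress_pca(zscore_columns(m))
  expect_equal(fit$explained_variance_ratio[1], 1)
})

test_that("PCA is invariant to row permutation up to the sign convention", {
  withr::local_seed(46)
  m <- tibble::tibble(
    isolate_id = paste0("iso", 1:6),
    a = rnorm(6), b = rnorm(6), c = rnorm(6), d = rnorm(6)
  )
  z <- zscore_columns(m)
  fit1 <- stress_pca(z)
  perm <- sample(6)
  fit2 <- stress_pca(z[perm, ])
  expect_equal(as.matrix(fit2$loadings[, -1]), as.matrix(fit1$loadings[, -1]),
               tolerance = 1e-9)
  reord <- fit2$scores[match(fit1$scores$isolate_id, fit2$scores$isolate_id), ]
  expect_equal(as.matrix(reord[, -1]), as.matrix(fit1$scores[, -1]), tolerance = 1e-9)
})

test_that("a dominant isolate is extreme on PC1 with same-sign loadings", {
  panel <- generate_stress_panel(n_isolates = 3, dominant = "M2", seed = 47)
  fit <- run_pca(panel)
  pc1 <- setNames(fit$scores$PC1, fit$scores$isolate_id)
  expect_equal(names(which.max(abs(pc1))), "M2")
  expect_equal(length(unique(sign(fit$loadings$PC1))), 1L)
})

test_that("tidy and glance expose scores, loadings, and variance shares", {
  panel <- generate_stress_panel(n_isolates = 4, dominant = "M2", seed = 48)
  fit <- run_pca(panel)
  expect_equal(nrow(tidy(fit, "scores")), 4 * 4)
  expect_equal(nrow(tidy(fit, "loadings")), 4 * 4)
  ev <- tidy(fit, "eigenvalues")
  expect_equal(ev$explained_variance_ratio, fit$explained_variance_ratio)
  g <- glance(fit)
  expect_equal(g$n_isolates, 4)
  expect_equal(g$pc1_ratio, fit$explained_variance_ratio[1])
  expect_s3_class(autoplot(fit), "ggplot")
})
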