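test_that("standardization yields exact z-scores and rejects constants", {
  expect_equal(as.vector(standardize_matrix(matrix(c(1, 2, 3)))), c(-1, 0, 1))
  z <- standardize_matrix(matrix(rnorm(40), 8, 5))
  expect_equal(unname(standardize_matrix(z)), unname(z), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(standardize_matrix(cbind(a = c(1, 1, 1), b = 1:3)), "a")
  expect_error(standardize_matrix(matrix(1, 1, 2)), "two observations")
})

test_that("correlation PCA matches a dense eigendecomposition oracle", {
  set.seed(101)
  for (i in 1:10) {
    x <- matrix(rnorm(30), 6, 5)
    colnames(x) <- paste0("M", 1:5)
    fit <- fit_pca(x)
    oracle <- eigen(cor(x), symmetric = TRUE)
    expect_equal(fit$eigenvalues, oracle$values, tolerance = 1e-10)
    expect_equal(sum(fit$eigenvalues), 5, tolerance = 1e-8)
    expect_equal(fit$variability, fit$eigenvalues / 5 * 100, tolerance = 1e-10)
    expect_equal(fit$cumulative, cumsum(fit$variability), tolerance = 1e-10)
    # loadings reproduce the correlation matrix when nothing is discarded
    expect_equal(fit$loadings %*% t(fit$loadings), cor(x), tolerance = 1e-8,
                 ignore_attr = TRUE)
    # sign convention: dominant loading of every component is positive
    expect_true(all(apply(fit$loadings, 2,
                          function(l) l[which.max(abs(l))] >= 0)))
  }
})

test_that("degenerate correlation structures give the expected spectra", {
  x <- cbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8))  # perfectly correlated
  fit <- fit_pca(x)
  expect_equal(fit$eigenvalues, c(2, 0), tolerance = 1e-10)

  # orthogonal equal-variance contrasts: identity correlation, all eigenvalues 1
  h <- cbind(c(1, 1, -1, -1), c(1, -1, 1, -1), c(1, -1, -1, 1))
  expect_equal(fit_pca(h)$eigenvalues, c(1, 1, 1), tolerance = 1e-10)

  # p > n-1: trailing eigenvalues exactly zero and never retained
  wide <- matrix(rnorm(3 * 5), 3, 5)
  fw <- fit_pca(wide)
  expect_equal(fw$eigenvalues[3:5], c(0, 0, 0))
  expect_lte(length(retain_components(fw, "kaiser")$eigenvalues), 2)
})

test_that("component retention follows kaiser or a fixed count", {
  dou <- case_study_pca()$DOU
  expect_equal(sum(dou$eigenvalues > 1), 2)
  set.seed(5)
  fit <- fit_pca(matrix(rnorm(60), 12, 5))
  kept <- retain_components(fit, "kaiser")
  expect_equal(length(kept$eigenvalues), max(1, sum(fit$eigenvalues > 1)))
  expect_equal(length(retain_components(fit, "fixed", k = 2)$eigenvalues), 2)
  expect_error(retain_components(fit, "fixed", k = 9), "between 1 and")

  # single dominant component: kaiser keeps exactly one
  strong <- matrix(rnorm(12), 12, 1) %*% t(rep(1, 4)) + 0.05 * matrix(rnorm(48), 12, 4)
  expect_equal(length(retain_components(fit_pca(strong), "kaiser")$eigenvalues), 1)
})

test_that("varimax rotation maximizes the criterion and preserves communalities", {
  varimax_crit <- function(L) {
    sq <- L^2
    sum(apply(sq, 2, function(s) mean(s^2) - mean(s)^2))
  }
  set.seed(202)
  for (i in 1:5) {
    fit <- retain_components(fit_pca(matrix(rnorm(48), 8, 6)), "fixed", k = 2)
    rot <- varimax_rotate(fit, normalize = FALSE)
    # communalities invariant
    expect_equal(rowSums(rot$loadings^2), rowSums(fit$loadings^2),
                 tolerance = 1e-8)
    # criterion nondecreasing and matching a brute-force angle grid search
    expect_gte(varimax_crit(rot$loadings), varimax_crit(fit$loadings) - 1e-12)
    thetas <- seq(0, pi / 2, by = 1e-4)
    best <- max(vapply(thetas, function(t) {
      R <- matrix(c(cos(t), sin(t), -sin(t), cos(t)), 2, 2)
      varimax_crit(fit$loadings %*% R)
    }, numeric(1)))
    expect_equal(varimax_crit(rot$loadings), best, tolerance = 1e-6)
  }

  # perfect simple structure is a fixed point (up to column order/sign)
  L <- rbind(c(0.9, 0), c(0.8, 0), c(0, 0.7), c(0, 0.6))
  fake <- structure(list(metals = paste0("M", 1:4), eigenvalues = colSums(L^2),
                         loadings = L, variability = colSums(L^2) / 4 * 100,
                         cumulative = cumsum(colSums(L^2) / 4 * 100),
                         rotation = "none", n_obs = 10), class = "factor_model")
  rot <- varimax_rotate(fake, normalize = FALSE)
  expect_equal(abs(unclass(rot$loadings)), abs(L), tolerance = 1e-6,
               ignore_attr = TRUE)

  one <- retain_components(fit_pca(matrix(rnorm(40), 8, 5)), "fixed", k = 1)
  expect_warning(same <- varimax_rotate(one), "identity")
  expect_equal(same$loadings, one$loadings)
})

test_that("bn weight is the reciprocal of the selected eigenvalue", {
  expect_equal(bn_weight(1.705), 0.58651, tolerance = 1e-5)
  expect_equal(bn_weight(1), 1)
  expect_equal(bn_weight(2.268), 0.44092, tolerance = 1e-5)
  fit <- fit_pca(cbind(a = c(1, 2, 3, 5), b = c(2, 1, 4, 4), c = c(9, 7, 1, 2)))
  expect_equal(bn_weight(fit), 1 / fit$eigenvalues[1])
  expect_equal(bn_weight(fit, component = 2), 1 / fit$eigenvalues[2])
  expect_error(bn_weight(fit, component = 9), "not retained")
  expect_error(bn_weight(-2), "positive")
})

test_that("per-site models use the periods-by-metals data of each site", {
  x <- case_study_concentrations()
  models <- site_pca(x, retain = NULL)
  expect_named(models, c("QUE", "DOU", "STB", "OKT", "QUR"))
  expect_equal(models$DOU$n_obs, 6)
  expect_equal(sum(models$DOU$eigenvalues), 5, tolerance = 1e-8)
  # oracle check on one site built by hand
  wide <- tidyr::pivot_wider(x[x$site == "QUE", c("period", "metal", "c")],
                             names_from = "metal", values_from = "c")
  oracle <- eigen(cor(as.matrix(wide[-1])), symmetric = TRUE)$values
  expect_equal(models$QUE$eigenvalues, oracle, tolerance = 1e-10)
})
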