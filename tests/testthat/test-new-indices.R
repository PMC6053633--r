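test_that("mHQ matches direct evaluation of its formula", {
  # expected values computed by writing the formula out long-hand
  expect_equal(mhq(4.8, 0.68, 4.21, 10),
               sqrt(4.8 * (1 / 0.68 + 1 / 4.21 + 1 / 10)), tolerance = 1e-12)
  expect_equal(mhq(4.8, 0.68, 4.21, 10), 2.946, tolerance = 5e-4)
  expect_equal(mhq(178, 35, 91.3, 250), 2.783, tolerance = 5e-4)
  expect_equal(mhq(0, 0.68, 4.21, 10), 0)
  s <- 1 / 0.68 + 1 / 4.21 + 1 / 10
  expect_equal(mhq(1 / s, 0.68, 4.21, 10), 1, tolerance = 1e-12)

  expect_error(mhq(-1, 0.68, 4.21, 10), "non-negative")
  expect_error(mhq(1, 0, 4.21, 10), "positive")
})

test_that("mHQ obeys monotonicity and the square-root scaling law", {
  set.seed(42)
  for (i in 1:20) {
    tel <- runif(1, 0.1, 50); pel <- tel * runif(1, 1.5, 5)
    sel <- pel * runif(1, 1.1, 3)
    c1 <- runif(1, 0.01, 300)
    expect_lt(mhq(c1, tel, pel, sel), mhq(c1 * 1.01, tel, pel, sel))
    expect_equal(mhq(4 * c1, tel, pel, sel), 2 * mhq(c1, tel, pel, sel),
                 tolerance = 1e-12)
  }
})

test_that("a missing SEL drops its term and is flagged in the table", {
  partial <- mhq(10, tel = 2, pel = 4, sel = NA)
  expect_equal(partial, sqrt(10 * (1 / 2 + 1 / 4)), tolerance = 1e-12)
  g <- tibble::tibble(metal = "Cd", tel = 2, pel = 4, sel = NA_real_)
  m <- matrix(10, 1, 1, dimnames = list("A", "Cd"))
  tab <- mhq_table(m, g)
  expect_true(tab$partial_guidelines)
  expect_error(mhq(1, NA, NA, NA), "at least one")
})

test_that("severity classification is total with left-closed boundaries", {
  expect_equal(classify_mhq(3.6), "Extreme severity of contamination")
  expect_equal(classify_mhq(0.3), "Nil to very low severity of contamination")
  expect_equal(classify_mhq(2.5), "High severity of contamination")
  # every printed cut point belongs to the upper class; epsilon below stays lower
  cuts <- c(0.5, 1.0, 1.5, 2.0, 2.5, 3.0, 3.5)
  for (i in seq_along(cuts)) {
    expect_equal(classify_mhq(cuts[i]), mhq_severity_classes$label[i + 1])
    expect_equal(classify_mhq(cuts[i] - 1e-9), mhq_severity_classes$label[i])
  }
  # totality: every non-negative value maps to exactly one of the 8 labels
  xs <- seq(0, 6, by = 0.01)
  expect_true(all(classify_mhq(xs) %in% mhq_severity_classes$label))
  expect_error(classify_mhq(-0.1), "non-negative")
})

test_that("ECI is the weighted mHQ sum with exact decomposition", {
  mh <- c(Cd = 2.946, Pb = 2.783, Cu = 1.270, Cr = 0.955, Ni = 0.461)
  r <- eci(mh, bn = 1 / 1.705)
  expect_equal(r$eci, sum(mh) / 1.705, tolerance = 1e-12)
  expect_equal(r$eci, 4.936, tolerance = 5e-4)
  expect_equal(sum(r$contributions), 100, tolerance = 1e-9)
  # reconstructing the index from contributions and the sum is exact
  expect_equal(r$bn * sum(r$contributions / 100 * r$sum_mhq), r$eci,
               tolerance = 1e-12)
  expect_equal(names(which.max(r$contributions)), "Cd")

  expect_equal(eci(2.0, 0.5)$eci, 1.0)
  expect_warning(z <- eci(c(a = 0, b = 0), 1), "uniform")
  expect_equal(z$eci, 0)
  expect_equal(unname(z$contributions), c(50, 50))
  expect_error(eci(numeric(0), 1), "at least one")
  expect_error(eci(1, 0), "positive")
})

test_that("ECI increases with any single mHQ at fixed bn", {
  set.seed(7)
  base <- runif(5, 0, 3)
  for (j in 1:5) {
    up <- base
    up[j] <- up[j] + 0.1
    expect_lt(eci(base, 0.5)$eci, eci(up, 0.5)$eci)
  }
})

test_that("contamination classification is total with left-closed boundaries", {
  expect_equal(classify_eci(5.06), "Considerably to highly contaminated")
  expect_equal(classify_eci(1.5), "Uncontaminated")
  expect_equal(classify_eci(3.46), "Slightly to moderately contaminated")
  for (i in seq_along(2:7)) {
    cut <- (2:7)[i]
    expect_equal(classify_eci(cut), eci_contamination_classes$label[i + 1])
    expect_equal(classify_eci(cut - 1e-9), eci_contamination_classes$label[i])
  }
  xs <- seq(0, 10, by = 0.05)
  expect_true(all(classify_eci(xs) %in% eci_contamination_classes$label))
  expect_error(classify_eci(-1), "non-negative")
})

test_that("metal ranking is descending with flagged alphabetical ties", {
  tbl <- tibble::tibble(site = "DOU",
                        metal = c("Cd", "Cr", "Cu", "Ni", "Pb"),
                        mhq = c(3.1, 0.95, 1.27, 0.46, 2.78))
  r <- rank_metals(tbl)
  expect_equal(r$ordering[[1]], c("Cd", "Pb", "Cu", "Cr", "Ni"))
  expect_equal(r$sequence, "Cd > Pb > Cu > Cr > Ni")
  expect_false(r$tied)

  tie <- tibble::tibble(site = "A", metal = c("Pb", "Cd"), mhq = c(2, 2))
  rt <- rank_metals(tie)
  expect_equal(rt$ordering[[1]], c("Cd", "Pb"))
  expect_true(rt$tied)

  single <- rank_metals(tibble::tibble(site = "A", metal = "Cd", mhq = 1))
  expect_equal(single$ordering[[1]], "Cd")
})
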