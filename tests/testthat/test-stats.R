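test_that("relative effects match exhaustive pair enumeration", {
  expect_equal(relative_effects(list(a = c(2, 4, 6), b = c(2, 4, 6)))["a", "b"],
               0.5)
  expect_equal(relative_effects(list(a = c(1, 2), b = c(3, 4)))["a", "b"], 1)
  # (1<2) + (1<3) + (3>2) + (3=3)/2 over 4 pairs
  expect_equal(relative_effects(list(a = c(1, 3), b = c(2, 3)))["a", "b"],
               0.625)

  set.seed(31)
  for (rep in 1:40) {
    sizes <- sample(1:6, 3, replace = TRUE)
    g <- lapply(sizes, function(n) sample(1:4, n, replace = TRUE))
    names(g) <- c("x", "y", "z")
    m <- relative_effects(g)
    for (i in 1:2) for (j in (i + 1):3) {
      expect_equal(m[i, j], enum_relative_effect(g[[i]], g[[j]]))
      expect_equal(m[i, j] + m[j, i], 1)
    }
  }
  expect_error(relative_effects(list(a = numeric(0), b = 1:3)), "empty")
})

test_that("Kruskal-Wallis wrapper reproduces the hand-ranked statistic", {
  expect_equal(kruskal_wallis(list(a = 1:5, b = 1:5))$statistic, 0)
  kw <- kruskal_wallis(list(a = c(1, 2, 3), b = c(4, 5, 6)))
  # ranks 1..6, H = 12/(6*7) * (2*( (2-3.5)^2 + (5-3.5)^2 )*3) with no ties
  expect_equal(kw$statistic, 3.857143, tolerance = 1e-6)
  expect_equal(kw$df, 1)

  # rank invariance under joint relabeling
  set.seed(32)
  v <- rnorm(30); lab <- sample(c("a", "b", "c"), 30, replace = TRUE)
  perm <- sample(30)
  h1 <- kruskal_wallis(split(v, lab))$statistic
  h2 <- kruskal_wallis(split(v[perm], lab[perm]))$statistic
  expect_equal(h1, h2)
})

test_that("Mann-Whitney U convention and identities hold", {
  mw <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(unname(mw$U), 0)   # no pair with first > second
  expect_equal(mw$method, "exact")
  a <- c(1, 5, 7); b <- c(1, 5, 7)
  expect_equal(mann_whitney(a, b)$p.value, 1, tolerance = 1e-9)
  set.seed(33)
  x <- rnorm(12); y <- rnorm(15)
  expect_equal(mann_whitney(x, y)$U + mann_whitney(y, x)$U, 12 * 15)
})

test_that("chi-square independence is plain Pearson with transposition symmetry", {
  r0 <- chi_square_independence(matrix(c(10, 10, 10, 10), 2))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$df, 1)

  tab <- matrix(c(40, 50, 8, 15, 112, 7), nrow = 3)
  # direct hand computation of sum((O-E)^2/E)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  want <- sum((tab - E)^2 / E)
  got <- chi_square_independence(tab)
  expect_equal(got$statistic, want, tolerance = 1e-12)
  expect_equal(got$df, 2)
  expect_equal(chi_square_independence(t(tab))$statistic, want,
               tolerance = 1e-12)

  expect_error(chi_square_independence(matrix(c(0, 0, 3, 4), 2)),
               "marginal")
  expect_error(chi_square_independence(matrix(c(1.5, 2, 3, 4), 2)),
               "integer")
})

test_that("percentage-bend correlation is robust to gross outliers", {
  x <- as.numeric(1:20)
  expect_equal(percentage_bend_correlation(x, x)$r_pb, 1)
  expect_equal(percentage_bend_correlation(x, -x)$r_pb, -1)

  set.seed(34)
  xx <- rnorm(50); yy <- rnorm(50)
  xx[50] <- 40; yy[50] <- 40   # one gross outlier off a null cloud
  r_pb <- percentage_bend_correlation(xx, yy)$r_pb
  r_pearson <- cor(xx, yy)
  expect_lt(abs(r_pb), abs(r_pearson))

  cst <- rep(1, 10)
  expect_true(percentage_bend_correlation(cst, rnorm(10))$undefined)
  expect_error(percentage_bend_correlation(1:4, 1:4), "at least 5")
  expect_error(percentage_bend_correlation(1:10, 1:10, beta = 0.7), "beta")
})
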