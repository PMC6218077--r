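test_that("RELL proportions are exact under strict dominance and symmetry", {
  # tree A better at every site: BP(A) = 1 at any scale
  mat <- cbind(A = rep(-1, 40), B = rep(-1.4, 40))
  for (r in c(0.5, 1, 1.4)) {
    bp <- rell_bp(mat, scale = r, B = 200, seed = 1)
    expect_equal(unname(bp["A"]), 1)
  }
  # identical trees split the credit with a warning
  same <- cbind(t1 = rnorm(30), t2 = 0)
  same[, 2] <- same[, 1]
  expect_warning(bp2 <- rell_bp(same, B = 100, seed = 1), "identical")
  expect_equal(unname(bp2), c(0.5, 0.5))
})

test_that("two-site RELL matches exact multinomial enumeration", {
  mat <- cbind(t1 = c(log(0.9), log(0.2)), t2 = c(log(0.5), log(0.5)))
  # resamples of 2 sites: {1,1} w.p. 1/4 -> t1; {1,2} w.p. 1/2 -> t2;
  # {2,2} w.p. 1/4 -> t2  =>  exactly (0.25, 0.75)
  B <- 40000
  got <- rell_bp(mat, scale = 1, B = B, seed = 7)
  se <- sqrt(0.25 * 0.75 / B)
  expect_lt(abs(got[["t1"]] - 0.25), 4 * se)
})

test_that("AU results are reproducible and rank-consistent", {
  set.seed(123)
  base <- rnorm(200, -3)
  mat <- cbind(h1 = base + rnorm(200, 0.01, 0.2),
               h2 = base, h3 = base + rnorm(200, -0.01, 0.2))
  a1 <- au_test(mat, B = 500, seed = 42)
  a2 <- au_test(mat, B = 500, seed = 42)
  expect_identical(a1, a2)
  expect_true(all(a1$au >= 0 & a1$au <= 1))
  expect_true(all(a1$np >= 0 & a1$np <= 1))
  expect_equal(sum(a1$np), 1, tolerance = 1e-9)
  expect_equal(sort(a1$rank), 1:3)
  # the best tree by lnL has the largest np (up to Monte-Carlo error)
  expect_equal(which.max(a1$np), which.min(a1$rank))
})

test_that("AU p-values are invariant to a constant shift of the whole matrix", {
  set.seed(5)
  base <- rnorm(150, -2.5)
  mat <- cbind(x = base + rnorm(150, 0, 0.15),
               y = base + rnorm(150, 0, 0.15))
  a1 <- au_test(mat, B = 400, seed = 9)
  a2 <- au_test(mat + 0.7, B = 400, seed = 9)
  expect_equal(a1$au, a2$au, tolerance = 1e-12)
  expect_equal(a1$np, a2$np, tolerance = 1e-12)
})

test_that("a strong per-site shift separates the AU p-values", {
  set.seed(31)
  n <- 1000
  base <- rnorm(n, -3, 0.5)
  noise <- function() rnorm(n, 0, 0.15)
  mat <- cbind(good = base + 0.05, alt1 = base, alt2 = base - 0.01) +
    cbind(noise(), noise(), noise())
  res <- au_test(mat, B = 1000, seed = 2)
  expect_gt(res$au[res$tree == "good"], 0.95)
  expect_true(all(res$au[res$tree != "good"] < 0.01))
})

test_that("column permutations of the same site set tie all trees", {
  set.seed(77)
  col <- rnorm(120, -2)
  mat <- cbind(p1 = col, p2 = col[sample(120)], p3 = col[sample(120)])
  res <- au_test(mat, B = 500, seed = 3)
  expect_true(all(res$au > 0.05))
})
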