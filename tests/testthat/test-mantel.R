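test_that("lower-triangle correlation behaves like Pearson on aligned labels", {
  A <- random_dist(5, seed = 1)
  expect_equal(lower_triangle_correlation(A, A), 1.0)

  # affine transform of the off-diagonal entries: still 1
  diag_fix <- unclass(A) * 2 + 1
  diag(diag_fix) <- 0
  B <- dist_matrix(diag_fix, labels = rownames(A))
  expect_equal(lower_triangle_correlation(A, B), 1.0)

  # textbook-formula oracle on a random pair
  C <- random_dist(5, seed = 2)
  expect_equal(lower_triangle_correlation(A, C),
               textbook_cor(lower_vec(A), lower_vec(C)))

  # vegan cross-check of the statistic
  D <- random_dist(9, seed = 3)
  E <- random_dist(9, seed = 4)
  veg <- suppressWarnings(vegan::mantel(as.dist(unclass(D)),
                                        as.dist(unclass(E)),
                                        permutations = 0))
  expect_equal(lower_triangle_correlation(D, E), unname(veg$statistic))

  expect_error(lower_triangle_correlation(A, random_dist(5, 1, letters[1:5])),
               "label sets differ")
  flat <- dist_matrix(matrix(1, 4, 4) - diag(4), labels = rownames(A)[1:4])
  expect_error(lower_triangle_correlation(flat, align_dist(A, rownames(A)[1:4])),
               "zero variance")
})

test_that("alignment is by label, never by index", {
  A <- random_dist(6, seed = 5)
  B <- random_dist(6, seed = 6)
  perm <- withr::with_seed(7, sample(6))
  B_shuffled <- dist_matrix(unclass(B)[perm, perm],
                            labels = rownames(B)[perm])
  expect_equal(lower_triangle_correlation(A, B_shuffled),
               lower_triangle_correlation(A, B))
  r1 <- mantel_test(A, B, seed = 1)
  r2 <- mantel_test(A, B_shuffled, seed = 1)
  expect_equal(r1$r_observed, r2$r_observed)
  expect_equal(r1$p_value, r2$p_value)
})

test_that("exhaustive Mantel p equals independent enumeration at n = 4", {
  A <- random_dist(4, seed = 11)
  B <- random_dist(4, seed = 12)
  res <- mantel_test(A, B)
  expect_true(res$exhaustive)
  expect_equal(res$n_permutations, 24)
  brute <- brute_exhaustive_mantel(A, B)
  expect_equal(res$r_observed, brute$r)
  expect_equal(res$p_value, brute$p)
  expect_equal(sort(res$null_r), sort(brute$r_all), tolerance = 1e-12)

  for (tl in c("greater", "less")) {
    expect_equal(mantel_test(A, B, tail = tl)$p_value,
                 brute_exhaustive_mantel(A, B, tail = tl)$p)
  }
})

test_that("identical matrices give r = 1 and the minimal attainable p", {
  A <- random_dist(6, seed = 13)
  res <- mantel_test(A, A)
  expect_equal(res$r_observed, 1.0)
  # p = proportion of relabelings tying the maximum (>= 1/720, small)
  expect_gte(res$p_value, 1 / factorial(6))
  expect_equal(res$p_value, mean(res$null_r >= 1 - 1e-12))
})

test_that("Monte-Carlo p converges to the exhaustive p", {
  A <- random_dist(5, seed = 14)
  B <- random_dist(5, seed = 15)
  exact <- mantel_test(A, B)$p_value
  mc <- mantel_test(A, B, n_permutations = 1e5, seed = 99, exhaustive_cap = 0)
  se <- sqrt(exact * (1 - exact) / 1e5)
  expect_false(mc$exhaustive)
  expect_lt(abs(mc$p_value - exact), 3 * se + 2 / 1e5)
  expect_gte(mc$p_value, 1 / (1e5 + 1))
})

test_that("two-sided p is bounded by the sum of one-sided p values", {
  A <- random_dist(7, seed = 16)
  B <- random_dist(7, seed = 17)
  ps <- vapply(c("two_sided", "greater", "less"), function(tl) {
    mantel_test(A, B, tail = tl)$p_value
  }, numeric(1))
  expect_lte(ps[["two_sided"]], ps[["greater"]] + ps[["less"]])
})

test_that("partial Mantel collapses to simple r when conditioning is orthogonal", {
  # build C uncorrelated with A and B by construction on 4 labels
  labs <- letters[1:4]
  base <- matrix(0, 4, 4, dimnames = list(labs, labs))
  tri <- lower.tri(base)
  mk <- function(v) {
    m <- base
    m[tri] <- v
    dist_matrix(m + t(m))
  }
  a <- c(1, 2, 3, 4, 5, 6)
  b <- c(2, 1, 4, 3, 6, 5)
  A <- mk(a); B <- mk(b)
  # residualize a random vector against {1, a, b} so the conditioning
  # triangle has exactly zero correlation with both others
  x <- cbind(1, a, b)
  w <- withr::with_seed(2, runif(6))
  v <- w - x %*% solve(crossprod(x), crossprod(x, w))
  C <- mk(as.numeric(v) + 10) # shift to keep entries positive
  expect_equal(textbook_cor(lower_vec(A), lower_vec(C)), 0, tolerance = 1e-10)
  expect_equal(textbook_cor(lower_vec(B), lower_vec(C)), 0, tolerance = 1e-10)
  res <- partial_mantel_test(A, B, C)
  expect_equal(res$r_observed, lower_triangle_correlation(A, B),
               tolerance = 1e-10)
  expect_equal(res$permuted_matrix, "A")
})

test_that("partial correlation equals the residual-regression oracle", {
  withr::with_seed(31, {
    for (rep in 1:50) {
      n <- sample(5:10, 1)
      A <- random_dist(n, seed = rep * 3 + 1)
      B <- random_dist(n, seed = rep * 3 + 2)
      C <- random_dist(n, seed = rep * 3 + 3)
      res <- partial_mantel_test(A, B, C, exhaustive_cap = 0,
                                 n_permutations = 99, seed = 1)
      oracle <- residual_partial_cor(lower_vec(A), lower_vec(B), lower_vec(C))
      expect_equal(res$r_observed, oracle, tolerance = 1e-10)
    }
  })
  # vegan cross-check of the partial statistic
  A <- random_dist(10, seed = 301); B <- random_dist(10, seed = 302)
  C <- random_dist(10, seed = 303)
  veg <- suppressWarnings(vegan::mantel.partial(
    as.dist(unclass(A)), as.dist(unclass(B)), as.dist(unclass(C)),
    permutations = 0))
  expect_equal(partial_mantel_test(A, B, C, n_permutations = 99, seed = 1,
                                   exhaustive_cap = 0)$r_observed,
               unname(veg$statistic), tolerance = 1e-12)
})

test_that("degenerate conditioning is an error", {
  A <- random_dist(5, seed = 41)
  B <- random_dist(5, seed = 42)
  expect_error(partial_mantel_test(A, B, A), "degenerate conditioning")
})
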