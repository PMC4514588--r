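test_that("log-ratio variance is zero for proportional series and symmetric", {
  set.seed(5)
  a <- exp(rnorm(30))
  expect_equal(vr_pair(a, 3 * a), 0)
  b <- exp(rnorm(30))
  expect_equal(vr_pair(a, b), vr_pair(b, a), tolerance = 1e-12)
  expect_error(vr_pair(a[1], b[1]), "at least 2")
  expect_error(vr_pair(a, -b), "positive")
  # Monte-Carlo recovery of a known log-ratio variance
  set.seed(6)
  r <- exp(rnorm(50000, sd = sqrt(0.85)))
  base <- exp(rnorm(50000))
  expect_equal(vr_pair(base * r, base), 0.85, tolerance = 0.02)
})

test_that("variation matrix is symmetric, coherent, and built from vr_pair", {
  set.seed(8)
  X <- rand_comp_matrix(40, 5)
  Tm <- variation_matrix(X)
  expect_true(isSymmetric(unclass(Tm)))
  expect_equal(unname(diag(Tm)), rep(0, 5))
  expect_true(all(Tm >= 0))
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(Tm[i, j], vr_pair(X[, i], X[, j]), tolerance = 1e-12)
  }
  # subcompositional coherence: a column subset gives the matching block
  sub <- variation_matrix(X[, c(1, 2, 3)])
  expect_equal(unclass(sub), unclass(Tm)[1:3, 1:3], tolerance = 1e-12)
  # proportional columns give a zero matrix
  P <- outer(exp(rnorm(10)), c(1, 2, 5))
  expect_equal(max(abs(variation_matrix(P))), 0, tolerance = 1e-12)
})

test_that("clr covariance from a variation matrix matches the empirical clr covariance", {
  Tz <- vr_matrix(rep(0, 10), paste0("w", 1:5))
  expect_equal(max(abs(clr_cov_from_vr(Tz))), 0)
  set.seed(9)
  X <- rand_comp_matrix(60, 5)
  Tm <- variation_matrix(X)
  S <- clr_cov_from_vr(Tm)
  expect_lt(max(abs(rowSums(S))), 1e-10)
  cl <- log(X) - rowMeans(log(X))
  expect_equal(S, cov(cl), tolerance = 1e-10, ignore_attr = TRUE)
  # round trip: T recovered from Sigma
  Tback <- outer(diag(S), rep(1, 5)) + outer(rep(1, 5), diag(S)) - 2 * S
  expect_equal(Tback, unclass(Tm), tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(clr_cov_from_vr(matrix(1, 3, 3)), "diagonal")
})

test_that("balance coefficients follow the two-group closed form", {
  b <- balance_coefficients(1, 2, 2)
  expect_equal(unname(b$coeffs), c(1, -1) / sqrt(2))
  b <- balance_coefficients(1, c(2, 3), 5)
  expect_equal(unname(b$coeffs),
               c(sqrt(2 / 3), -sqrt(2 / 3) / 2, -sqrt(2 / 3) / 2, 0, 0),
               tolerance = 1e-12)
  set.seed(10)
  for (rep in 1:10) {
    D <- sample(3:7, 1)
    k <- sample(2:D, 1)
    S <- sample(D, k)
    plus <- S[seq_len(sample(k - 1, 1))]
    b <- balance_coefficients(plus, setdiff(S, plus), D)
    expect_lt(abs(sum(b$coeffs)), 1e-12)
    expect_equal(sum(b$coeffs^2), 1, tolerance = 1e-12)
  }
  expect_error(balance_coefficients(1, 1, 3), "overlap")
  expect_error(balance_coefficients(integer(0), 1, 3), "nonempty")
})

test_that("balance values equal the direct two-group formula", {
  X <- matrix(rep(0.2, 10), 2, 5)
  b <- balance_coefficients(c(1, 4), c(2, 5), 5)
  expect_equal(balance_values(X, b), c(0, 0))
  set.seed(12)
  X <- rand_comp_matrix(15, 5)
  bij <- balance_coefficients(2, 4, 5)
  expect_equal(balance_values(X, bij), log(X[, 2] / X[, 4]) / sqrt(2),
               tolerance = 1e-12)
  for (rep in 1:8) {
    S <- sample(5, sample(2:5, 1))
    plus <- S[seq_len(sample(length(S) - 1, 1))]
    minus <- setdiff(S, plus)
    b <- balance_coefficients(plus, minus, 5)
    direct <- apply(X, 1, oracle_balance_value, plus = plus, minus = minus)
    expect_equal(balance_values(X, b), direct, tolerance = 1e-12)
  }
})

test_that("in-sample identity: var of balance values == -1/2 a'Ta", {
  set.seed(13)
  for (rep in 1:10) {
    D <- sample(4:6, 1)
    X <- rand_comp_matrix(25, D)
    Tm <- variation_matrix(X)
    S <- sample(D, sample(2:D, 1))
    plus <- S[seq_len(sample(length(S) - 1, 1))]
    b <- balance_coefficients(plus, setdiff(S, plus), D)
    expect_equal(var(balance_values(X, b)), balance_variance_from_vr(Tm, b),
                 tolerance = 1e-10)
  }
})

test_that("balance enumeration matches the closed-form count and lists no duplicates", {
  expect_length(enumerate_balances(2, 2), 1)
  expect_length(enumerate_balances(3, 2:3), 6)
  expect_length(enumerate_balances(5, 2:5), 90)
  for (D in 3:6) {
    bals <- enumerate_balances(D, 2:D)
    expect_length(bals, sum(choose(D, 2:D) * (2^((2:D) - 1) - 1)))
    keys <- vapply(bals, function(b) paste(paste(b$plus, collapse = ","), "|",
                                           paste(b$minus, collapse = ",")), "")
    expect_false(any(duplicated(keys)))
    # canonical orientation: "+" group holds the smallest involved index
    expect_true(all(vapply(bals, function(b) min(b$plus) < min(b$minus), TRUE)))
  }
  expect_error(enumerate_balances(5, 1:3), "sizes")
})

test_that("balance screen ranks by variance and is zero for proportional data", {
  P <- outer(exp(rnorm(12)), c(1, 2, 5, 9))
  scr <- balance_screen(P)
  expect_true(all(abs(scr$variance) < 1e-12))
  set.seed(14)
  X <- rand_comp_matrix(30, 5)
  scr <- balance_screen(X)
  expect_equal(nrow(scr), 90)
  expect_true(!is.unsorted(scr$variance))
  expect_true(all(scr$variance >= -1e-12))
  expect_setequal(names(scr), c("rank", "variance", "size", "r", "s",
                                "plus_parts", "minus_parts"))
  # screening the data table and its variation matrix agree
  scr2 <- balance_screen(variation_matrix(X))
  expect_equal(scr$variance, scr2$variance, tolerance = 1e-10)
})

test_that("an SBP yields an orthonormal basis with D-1 balances", {
  out <- sbp_basis(matrix(c(1, -1), 1, 2))
  expect_length(out$balances, 1)
  expect_equal(unname(out$basis), matrix(c(1, -1) / sqrt(2), 1, 2))
  signs5 <- rbind(
    c(1, 1, 1, -1, -1),
    c(1, -1, -1, 0, 0),
    c(0, 1, -1, 0, 0),
    c(0, 0, 0, 1, -1)
  )
  out <- sbp_basis(signs5)
  expect_length(out$balances, 4)
  G <- tcrossprod(out$basis)
  expect_equal(G, diag(4), tolerance = 1e-12)
  expect_lt(max(abs(rowSums(out$basis))), 1e-12)
  # invalid: a split that is not nested
  bad <- rbind(c(1, 1, -1, -1), c(1, -1, 1, -1), c(0, 0, 1, -1))
  expect_error(sbp_basis(bad), "not a valid")
})
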