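test_that("forward DCT matches direct evaluation of the cosine sum", {
  expect_equal(dct_forward(rep(0, 16)), rep(0, 16))
  # constant window: only the k = 0 term survives, X_0 = N
  expect_equal(dct_forward(rep(1, 4))[1], 4)
  expect_lt(max(abs(dct_forward(rep(1, 4))[2:4])), 1e-12)
  # impulse x_2 = 5, N = 4: X_1 = 5 cos(5 pi / 8)
  x <- c(0, 0, 5, 0)
  expect_equal(dct_forward(x)[2], 5 * cos(5 * pi / 8))
  # random windows against the term-by-term reference
  set.seed(11)
  for (N in c(1, 2, 7, 90)) {
    v <- rnorm(N)
    expect_lt(max(abs(dct_forward(v) - dct_reference(v))), 1e-9)
  }
  expect_error(dct_forward(numeric(0)), "empty")
})

test_that("DCT is linear and inverts to 1e-9", {
  set.seed(21)
  x <- rnorm(90); y <- rnorm(90)
  lhs <- dct_forward(2.5 * x - 1.3 * y)
  rhs <- 2.5 * dct_forward(x) - 1.3 * dct_forward(y)
  expect_lt(max(abs(lhs - rhs)), 1e-9)

  expect_lt(max(abs(dct_inverse(dct_forward(x)) - x)), 1e-9)
  expect_equal(dct_inverse(dct_forward(rep(0, 90))), rep(0, 90))
  # integer count window recovers exactly (vs explicit matrix solve)
  w <- numeric(90); w[41] <- 12
  expect_lt(max(abs(dct_inverse(dct_forward(w)) - w)), 1e-9)
  expect_lt(max(abs(solve(dct_basis(12), dct_forward(1:12)) - 1:12)), 1e-9)
})

test_that("zero entries contribute nothing to any coefficient", {
  # the per-sample decomposition that justifies fictitious zeroes
  expect_true(zero_contribution_check(rep(0, 30), 0:29))
  expect_true(zero_contribution_check(rnorm(30), integer(0)))
  set.seed(31)
  for (i in 1:100) {
    v <- numeric(90)
    nz <- sample(90, sample(1:5, 1))
    v[nz] <- sample(1:120, length(nz), replace = TRUE)
    expect_true(zero_contribution_check(v, setdiff(0:89, nz - 1L)))
  }
  expect_error(zero_contribution_check(c(1, 0), 0), "non-zero")
})

test_that("coefficient selection is uniform, distinct and seed-deterministic", {
  sel <- select_coefficients(90, 30, seed = 7)
  expect_length(sel$indices, 30)
  expect_false(anyDuplicated(sel$indices) > 0)
  expect_true(all(sel$indices >= 0 & sel$indices <= 89))
  expect_identical(sel, select_coefficients(90, 30, seed = 7))
  expect_false(identical(sel$indices,
                         select_coefficients(90, 30, seed = 8)$indices))
  expect_equal(select_coefficients(5, 5, seed = 1)$indices, 0:4)
  expect_error(select_coefficients(10, 11, seed = 1), "n_coeffs")
  expect_true(0L %in% select_coefficients(90, 3, seed = 99,
                                          include_dc = TRUE)$indices)
})

test_that("window reduction picks the selected coefficients in order", {
  X <- dct_forward(c(3, 1, 4, 1, 5, 9, 2, 6))
  full <- select_coefficients(8, 8, seed = 1)
  expect_equal(reduce_window(X, full), X)
  one <- structure(list(indices = 0L, seed = 1),
                   class = "coefficient_selection")
  expect_equal(reduce_window(dct_forward(rep(2, 10)), one), 20)
  sel <- select_coefficients(8, 3, seed = 5)
  expect_equal(reduce_window(X, sel), X[sel$indices + 1L])
  bad <- structure(list(indices = 9L, seed = 1),
                   class = "coefficient_selection")
  expect_error(reduce_window(X, bad), "range")
})

test_that("incremental sliding spectra agree with direct recomputation", {
  # constant grid: every window has the same spectrum
  g <- grid_from_values(rep(3, 120))
  sp <- sliding_spectra(g, 90)
  expect_equal(nrow(sp$coefficients), 31)
  expect_lt(max(abs(sweep(sp$coefficients, 2, sp$coefficients[1, ]))), 1e-9)
  # sparse random grid: incremental equals direct everywhere
  set.seed(41)
  v <- numeric(400)
  v[sample(400, 25)] <- sample(1:120, 25, replace = TRUE)
  d <- sliding_spectra(v, 90, mode = "direct")
  i <- sliding_spectra(v, 90, mode = "incremental")
  expect_equal(d$starts, i$starts)
  expect_lt(max(abs(d$coefficients - i$coefficients)), 1e-6)
  # dense grid too (worst case for the active-set path)
  vd <- rnorm(150)
  dd <- sliding_spectra(vd, 90, mode = "direct")
  ii <- sliding_spectra(vd, 90, mode = "incremental")
  expect_lt(max(abs(dd$coefficients - ii$coefficients)), 1e-6)
  # single window when grid length equals the window
  expect_equal(nrow(sliding_spectra(rep(1, 90), 90)$coefficients), 1)
  expect_error(sliding_spectra(rep(1, 50), 90), "longer")
})

test_that("basis pursuit recovers the l1-minimal solution on small systems", {
  # fully measured: equals the exact inverse transform
  set.seed(51)
  x0 <- numeric(16); x0[c(3, 11)] <- c(7, -2)
  X <- dct_forward(x0)
  expect_lt(max(abs(basis_pursuit(X, 0:15, 16) - x0)), 1e-9)

  # n = 8 impulse from 4 random rows; oracle enumerates all single-support
  # candidates and confirms the returned solutions reach the smallest l1
  # norm (the optimum need not be unique at this few measurements, so the
  # two routes are compared on the l1 norm and feasibility, not pointwise)
  x0 <- numeric(8); x0[3] <- 7
  A <- dct_basis(8)
  for (s in 1:5) {
    set.seed(100 + s)
    rows <- sort(sample(0:7, 4))
    b <- drop(A[rows + 1, ] %*% x0)
    xr <- basis_pursuit(b, rows, 8, method = "lp")
    cand_norms <- vapply(1:8, function(j) {
      a <- A[rows + 1, j]
      c <- b[which.max(abs(a))] / a[which.max(abs(a))]
      if (max(abs(a * c - b)) < 1e-8) abs(c) else Inf
    }, numeric(1))
    expect_equal(sum(abs(xr)), min(cand_norms), tolerance = 1e-7)
    xa <- basis_pursuit(b, rows, 8, method = "admm")
    expect_equal(sum(abs(xa)), min(cand_norms), tolerance = 1e-7)
    expect_lt(max(abs(A[rows + 1, ] %*% xa - b)), 1e-8)
  }
  expect_error(basis_pursuit(numeric(0), integer(0), 8), "no measurements")
  expect_error(basis_pursuit(c(1, 1), c(0, 0), 8), "duplicate")
  expect_error(basis_pursuit(c(1, 2), c(1, 2), 2), "range")
})

test_that("recovery probability does not decrease with more measurements", {
  n <- 128; k <- 4
  fractions <- c(0.15, 0.45)
  success <- sapply(fractions, function(fr) {
    hits <- 0
    for (s in 1:8) {
      set.seed(1000 + s)
      x0 <- numeric(n); x0[sample(n, k)] <- sample(5:50, k, replace = TRUE)
      rows <- sort(sample(0:(n - 1), round(fr * n)))
      b <- drop(dct_basis(n)[rows + 1, ] %*% x0)
      xr <- tryCatch(basis_pursuit(b, rows, n, method = "admm"),
                     error = function(e) rep(Inf, n))
      hits <- hits + (max(abs(xr - x0)) < 1e-6)
    }
    hits
  })
  expect_true(success[2] >= success[1])
  expect_equal(success[2], 8)   # nearly half the rows: always recovers
})

test_that("top spectral coefficients out-carry random time samples", {
  set.seed(61)
  wins <- 0; fracs <- numeric(40)
  for (i in 1:40) {
    v <- numeric(90)
    v[sample(90, 4)] <- sample(5:120, 4, replace = TRUE)
    X <- dct_forward(v)
    fracs[i] <- sum(sort(X^2, decreasing = TRUE)[1:30]) / sum(X^2)
    time_frac <- sum(v[sample(90, 30)]^2) / sum(v^2)
    wins <- wins + (fracs[i] > time_frac)
  }
  # the best 30 of 90 coefficients always carry at least their 1/3 share of
  # the spectral energy and in practice far more, beating 30 random
  # time-domain samples in the vast majority of windows
  expect_true(all(fracs >= 1 / 3))
  expect_gt(mean(fracs), 0.7)
  expect_gt(wins, 33)
})
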