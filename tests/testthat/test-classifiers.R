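test_that("two symmetric points give the canonical maximum-margin line", {
  X <- matrix(c(-1, 1), ncol = 1)
  m <- svm_train(X, c(-1, 1), C = 1e6)
  expect_equal(m$w, 1, tolerance = 1e-6)
  expect_equal(m$b, 0, tolerance = 1e-6)
  expect_equal(m$margin, 1, tolerance = 1e-6)
  expect_lt(max(m$slack), 1e-6)
  expect_equal(svm_predict(m, matrix(c(-3, 3), ncol = 1)), c(-1L, 1L))
  # a point exactly on the hyperplane is called normal
  expect_equal(svm_predict(m, matrix(0, ncol = 1)), -1L)
})

test_that("separable 2-d solutions match the support-set enumeration oracle", {
  set.seed(71)
  for (rep in 1:5) {
    Xp <- cbind(rnorm(5, 3), rnorm(5, 3))
    Xn <- cbind(rnorm(5, -3), rnorm(5, -3))
    X <- rbind(Xp, Xn); y <- rep(c(1, -1), each = 5)
    m <- svm_train(X, y, C = 1e6)
    oracle <- hard_margin_oracle(X, y)
    expect_false(is.null(oracle))
    expect_equal(m$w, oracle$w, tolerance = 1e-4)
    expect_equal(m$b, oracle$b, tolerance = 1e-4)
    # reflecting a point through the hyperplane mirrors its decision value
    x <- X[1, ]
    xm <- x - 2 * (sum(m$w * x) + m$b) / sum(m$w^2) * m$w
    expect_equal(svm_decision(m, xm), -svm_decision(m, x), tolerance = 1e-4)
  }
})

test_that("overlapping classes with small C produce slack above one", {
  set.seed(81)
  X <- rbind(cbind(rnorm(20, 0.3), rnorm(20)), cbind(rnorm(20, -0.3), rnorm(20)))
  y <- rep(c(1, -1), each = 20)
  m <- svm_train(X, y, C = 0.1)
  expect_true(any(m$slack > 1))             # misclassified vectors exist
  mis <- which(y * svm_decision(m, X) < 0)
  expect_true(all(m$slack[mis] > 1))
  # training error is bounded by the total slack
  expect_lte(length(mis) / length(y), sum(m$slack) / length(y))
})

test_that("dual solution matches the reference QP objective to 1e-6 relative", {
  skip_if_not_installed("e1071")
  set.seed(91)
  for (i in 1:20) {
    n <- 12; p <- 3
    X <- matrix(rnorm(n * p), n, p) +
      outer(rep(c(1, -1), each = n / 2), rnorm(p))
    y <- rep(c(1, -1), each = n / 2)
    C <- sample(c(0.5, 1, 10), 1)
    m <- svm_train(X, y, C = C)
    ref <- e1071::svm(X, factor(y), scale = FALSE, kernel = "linear",
                      cost = C, tolerance = 1e-12, shrinking = FALSE)
    wr <- drop(t(ref$coefs) %*% ref$SV)
    br <- -ref$rho
    # libsvm orients w by its internal level order; the correctly oriented
    # sign gives the smaller (optimal) primal objective
    obj_ref <- min(svm_primal_objective(wr, br, X, y, C, optimize_b = TRUE),
                   svm_primal_objective(-wr, -br, X, y, C, optimize_b = TRUE))
    # certificate: our feasible dual value bounds the optimum from below,
    # so a tiny duality gap proves our primal value optimal
    K <- X %*% t(X); ay <- m$alpha * y
    dual <- sum(m$alpha) - 0.5 * drop(crossprod(ay, K %*% ay))
    expect_lte(m$objective - dual, 1e-7 * (1 + abs(m$objective)))
    expect_lt(abs(m$objective - obj_ref), 1e-6 * (1 + abs(obj_ref)))
  }
})

test_that("single-class input is rejected with a pointer to MVE", {
  X <- matrix(rnorm(10), 5, 2)
  expect_error(svm_train(X, rep(1, 5)), "mve_fit")
  expect_error(svm_train(X, rep(1, 5), kernel = "rbf"), "single class")
  m <- svm_train(rbind(X, X + 5), rep(c(-1, 1), each = 5))
  expect_error(svm_predict(m, c(1, 2, 3)), "dimension")
})

test_that("nonlinear kernels classify a radially separable set", {
  set.seed(101)
  th <- runif(40, 0, 2 * pi)
  inner <- cbind(0.5 * cos(th[1:20]), 0.5 * sin(th[1:20]))
  outer_ <- cbind(3 * cos(th[21:40]), 3 * sin(th[21:40]))
  X <- rbind(inner, outer_); y <- rep(c(1, -1), each = 20)
  m <- svm_train(X, y, C = 10, kernel = "rbf", gamma = 1)
  expect_equal(unname(svm_predict(m, X)), y)
})

test_that("MVE recovers symmetric fixtures to 1e-4", {
  # four unit points: the minimum-area ellipse is the unit circle
  P <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  m <- mve_fit(P, tolerance = 1e-9)
  expect_equal(m$center, c(0, 0), tolerance = 1e-4)
  expect_equal(m$shape, diag(2), tolerance = 1e-4)
  # equilateral triangle inscribed in the unit circle: same circle
  ang <- c(0, 2 * pi / 3, 4 * pi / 3) + 0.3
  Tr <- cbind(cos(ang), sin(ang))
  mt <- mve_fit(Tr, tolerance = 1e-9)
  expect_equal(mt$center, c(0, 0), tolerance = 1e-4)
  expect_equal(mt$shape, diag(2), tolerance = 1e-4)
  expect_equal(mve_volume(mt), pi, tolerance = 1e-3)
})

test_that("MVE contains all training points and beats a dense grid oracle", {
  set.seed(111)
  for (i in 1:10) {
    P <- matrix(rnorm(20), 10, 2) %*% matrix(c(2, 0.5, 0, 1), 2) +
      rep(rnorm(2), each = 10)
    m <- mve_fit(P, tolerance = 1e-8)
    expect_true(all(mve_distance(m, P) <= 1 + 1e-7))
    expect_true(all(mve_classify(m, P) == "normal"))
    expect_lte(mve_volume(m), ellipse_grid_oracle(P) * (1 + 1e-6))
  }
})

test_that("tighter tolerance never enlarges the ellipsoid", {
  set.seed(121)
  P <- matrix(rnorm(30), 15, 2)
  v_loose <- mve_volume(mve_fit(P, tolerance = 1e-3))
  v_tight <- mve_volume(mve_fit(P, tolerance = 1e-7))
  expect_lte(v_tight, v_loose * (1 + 1e-6))
})

test_that("MVE classification geometry and degenerate inputs behave", {
  set.seed(131)
  P <- matrix(rnorm(40), 20, 2)
  m <- mve_fit(P)
  expect_equal(mve_classify(m, m$center), "normal")
  ev <- eigen(m$shape)
  far <- m$center + 10 * ev$vectors[, 1] / sqrt(ev$values[1])
  expect_equal(mve_classify(m, far), "outlier")
  expect_error(mve_distance(m, c(1, 2, 3)), "dimension")
  # rank-deficient cloud: regularization engages with a warning
  Pd <- cbind(rnorm(10), 0)
  expect_warning(md <- mve_fit(Pd), "degenerate")
  expect_true(all(mve_distance(md, Pd) <= 1 + md$tolerance))
})

test_that("delay-network grid search is deterministic and finds structure", {
  # constant series: trivially learnable
  m0 <- ann_fit_grid(rep(5, 60), f_range = 1:2, d_range = 1:2, seed = 3)
  expect_lt(m0$nmse, 1e-4)
  # noiseless oscillatory two-lag recurrence (complex roots, so no 1-lag
  # function reproduces it): a d >= 2 model beats the best d = 1 model
  y <- numeric(40); y[1] <- 1; y[2] <- -1
  for (t in 3:40) y[t] <- 0.9 * y[t - 1] - 0.5 * y[t - 2]
  # least-squares oracle: d = 2 is exactly solvable, d = 1 is not
  d2 <- lm(y[3:40] ~ y[2:39] + y[1:38])
  d1 <- lm(y[2:40] ~ y[1:39])
  expect_lt(mean(resid(d2)^2), 1e-20)
  expect_gt(mean(resid(d1)^2) / var(y[2:40]), 1e-2)
  m <- ann_fit_grid(y, f_range = 1:3, d_range = 1:3, seed = 5)
  expect_gte(m$d, 2)
  best_d1 <- min(m$grid$nmse[m$grid$d == 1])
  expect_lt(m$nmse, best_d1)
  # determinism given the seed
  m2 <- ann_fit_grid(y, f_range = 1:3, d_range = 1:3, seed = 5)
  expect_identical(m$fit$wts, m2$fit$wts)
  expect_identical(m$grid, m2$grid)
  expect_error(ann_fit_grid(c(1, 2), d_range = 5), "short")
})

test_that("neural alarm triggers on a learned rising pattern only", {
  set.seed(141)
  # zero history, zero-trained model: no alarm
  mz <- ann_fit_grid(rep(0, 50), f_range = 1, d_range = 2, seed = 1)
  expect_equal(ann_alarm(mz, rep(0, 10), event_threshold = 10), "none")
  # a model trained on exponential run-ups extrapolates them across 10
  ramp <- rep(c(exp(0.35 * (1:20)), rep(0, 10)), 4)
  mr <- ann_fit_grid(ramp, f_range = 3, d_range = 3, seed = 2)
  expect_equal(ann_alarm(mr, exp(0.35 * (12:19)), event_threshold = 10,
                         horizon = 10), "alarm")
  # forecasts below the threshold stay quiet
  expect_equal(ann_alarm(mz, rep(0, 10), event_threshold = 10,
                         horizon = 5), "none")
  expect_error(ann_forecast(mr, 1, horizon = 2), "recent")
})
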