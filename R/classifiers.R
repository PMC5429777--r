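## Soft-margin SVM ----------------------------------------------------------

svm_kernel <- function(X, Y, kernel, gamma, degree, coef0) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  switch(kernel,
    linear = X %*% t(Y),
    rbf = {
      d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * X %*% t(Y)
      exp(-gamma * pmax(d2, 0))
    },
    polynomial = (gamma * X %*% t(Y) + coef0)^degree,
    stop("unknown kernel: ", kernel))
}

# Refine a near-optimal dual solution: with the active set read off the
# solver output, the free coefficients and b satisfy a linear KKT system
# exactly (margin constraints active, equality constraint). Accepted only
# when the polished point stays in the box and violates no KKT condition.
.svm_polish <- function(alpha, K, y, C, tol = 1e-6) {
  amax <- max(alpha)
  if (amax <= 0) return(list(alpha = alpha, b = NA_real_))
  free <- which(alpha > tol * amax & alpha < C - tol * min(C, amax))
  atC <- which(alpha >= C - tol * min(C, amax))
  if (!length(free)) {
    # every multiplier at a bound: alpha is {0, C}-valued and b lies in the
    # KKT interval; take its midpoint and validate
    a_new <- ifelse(seq_along(alpha) %in% atC, C, 0)
    if (abs(sum(a_new * y)) > 1e-9 * max(C, 1))
      return(list(alpha = alpha, b = NA_real_))
    f0 <- drop(K %*% (a_new * y))
    lo <- max((y - f0)[(y == 1 & a_new == 0) | (y == -1 & a_new == C)], -Inf)
    up <- min((y - f0)[(y == -1 & a_new == 0) | (y == 1 & a_new == C)], Inf)
    if (!is.finite(lo) || !is.finite(up) || lo > up + 1e-7)
      return(list(alpha = alpha, b = NA_real_))
    return(list(alpha = a_new, b = (lo + up) / 2))
  }
  # rows: y_i-margin stationarity for free i; last row: equality constraint
  M <- rbind(cbind(sweep(K[free, free, drop = FALSE], 2, y[free], "*"), 1),
             c(y[free], 0))
  rhs <- c(y[free] - if (length(atC))
             drop(K[free, atC, drop = FALSE] %*% (C * y[atC])) else 0,
           -sum(C * y[atC]))
  sol <- tryCatch(qr.solve(M, rhs), error = function(e) NULL)
  if (is.null(sol)) return(list(alpha = alpha, b = NA_real_))
  a_new <- alpha
  a_new[free] <- sol[seq_along(free)]
  a_new[-c(free, atC)] <- 0
  a_new[atC] <- C
  b_new <- sol[length(sol)]
  slackK <- 1e-7 * (1 + max(abs(K)))
  if (any(a_new < -slackK) || any(a_new > C + slackK))
    return(list(alpha = alpha, b = NA_real_))
  a_new <- pmin(pmax(a_new, 0), C)
  fit <- drop(K %*% (a_new * y)) + b_new
  marg <- y * fit
  zero <- setdiff(seq_along(alpha), c(free, atC))
  if ((length(zero) && any(marg[zero] < 1 - 1e-6)) ||
      (length(atC) && any(marg[atC] > 1 + 1e-6)))
    return(list(alpha = alpha, b = NA_real_))
  list(alpha = a_new, b = b_new)
}

#' Train a soft-margin support vector machine
#'
#' Solves the two-class soft-margin problem
#' \deqn{\min \tfrac12\|w\|^2 + C\sum_i S_i \quad
#'       \mathrm{s.t.}\ y_i(w^\top x_i + b) \ge 1 - S_i,\ S_i \ge 0}
#' through its dual, a box-constrained quadratic program solved exactly
#' with \code{quadprog}. The slack \eqn{S_i} is 0 for a well-classified
#' vector, in (0, 1] inside the separating band, and above 1 for a
#' misclassified vector; larger \code{C} penalizes misclassification
#' harder and narrows the margin (for linear separation the margin is
#' \eqn{1/\|w\|}).
#'
#' @param X n x m numeric feature matrix (rows are training vectors).
#' @param y Labels, +1 (contaminated) / -1 (normal).
#' @param C Misclassification weight, default 1.
#' @param kernel \code{"linear"} (default), \code{"rbf"} or
#'   \code{"polynomial"}.
#' @param gamma Kernel width / scale; default \code{1/ncol(X)}.
#' @param degree Polynomial degree, default 3.
#' @param coef0 Polynomial offset, default 0.
#' @return Object of class \code{swell_svm}: dual coefficients
#'   \code{alpha}, intercept \code{b}, normal vector \code{w} (linear
#'   kernel only), per-vector \code{slack}, primal \code{objective}, the
#'   support vectors and kernel settings.
#' @export
svm_train <- function(X, y, C = 1, kernel = c("linear", "rbf", "polynomial"),
                      gamma = NULL, degree = 3, coef0 = 0) {
  kernel <- match.arg(kernel)
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  stopifnot(length(y) == n, n >= 2, C > 0)
  if (!all(y %in% c(-1, 1))) stop("labels must be +1/-1")
  if (length(unique(y)) < 2L)
    stop("training data holds a single class; use mve_fit for ",
         "one-class (novelty) modeling")
  if (is.null(gamma)) gamma <- 1 / ncol(X)
  K <- svm_kernel(X, X, kernel, gamma, degree, coef0)
  # Dual: max 1'a - a'(yy' * K)a/2, 0 <= a <= C, y'a = 0. The kernel matrix
  # is only PSD (duplicate windows are common), so a small ridge keeps the
  # active-set solver happy; the KKT polish below removes its bias.
  D <- (y %o% y) * K
  sol <- NULL
  for (ridge in 1e-7 * (mean(diag(K)) + 1) * c(1, 100, 1e4)) {
    sol <- tryCatch(quadprog::solve.QP(
      Dmat = D + diag(ridge, n), dvec = rep(1, n),
      Amat = cbind(y, diag(n), -diag(n)),
      bvec = c(0, rep(0, n), rep(-C, n)), meq = 1),
      error = function(e) NULL)
    if (!is.null(sol)) break
  }
  if (is.null(sol)) stop("dual QP solver failed on this training set")
  alpha <- pmin(pmax(sol$solution, 0), C)
  # the ridged solve can blur the active set; try several thresholds and
  # keep the valid KKT-polished solution with the best primal objective
  primal <- function(a, b) {
    ay <- a * y
    0.5 * drop(crossprod(ay, K %*% ay)) +
      C * sum(pmax(0, 1 - y * (drop(K %*% ay) + b)))
  }
  polished <- list(alpha = alpha, b = NA_real_)
  best_obj <- Inf
  for (tol in c(1e-6, 1e-4, 1e-3, 1e-2, 5e-2)) {
    pol <- .svm_polish(alpha, K, y, C, tol)
    if (!is.na(pol$b)) {
      obj <- primal(pol$alpha, pol$b)
      if (obj < best_obj) { best_obj <- obj; polished <- pol }
    }
  }
  alpha <- polished$alpha
  f_no_b <- drop(K %*% (alpha * y))
  b <- if (!is.na(polished$b)) polished$b else {
    amax <- max(alpha)
    free <- alpha > 1e-6 * amax & alpha < C - 1e-6 * min(C, amax)
    if (any(free)) mean(y[free] - f_no_b[free]) else {
      # no free vector: b is any value between the KKT bounds
      up <- min((y - f_no_b)[(y == -1 & alpha < C) | (y == 1 & alpha > 0)],
                Inf)
      lo <- max((y - f_no_b)[(y == 1 & alpha < C) | (y == -1 & alpha > 0)],
                -Inf)
      if (is.finite(lo) && is.finite(up)) (lo + up) / 2 else 0
    }
  }
  f <- f_no_b + b
  slack <- pmax(0, 1 - y * f)
  wnorm2 <- drop(crossprod(alpha * y, K %*% (alpha * y)))
  model <- structure(list(
    alpha = alpha, b = b, C = C, kernel = kernel, gamma = gamma,
    degree = degree, coef0 = coef0, X = X, y = y, slack = slack,
    w = if (kernel == "linear") drop(crossprod(X, alpha * y)) else NULL,
    objective = wnorm2 / 2 + C * sum(slack),
    margin = if (kernel == "linear" && wnorm2 > 0) 1 / sqrt(wnorm2) else NA_real_),
    class = "swell_svm")
  model
}

#' SVM decision values
#'
#' @param model A \code{\link{svm_train}} model.
#' @param x Feature vector or matrix (rows are cases).
#' @return Numeric decision value(s) \eqn{w^\top x + b}.
#' @export
svm_decision <- function(model, x) {
  x <- if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
  if (ncol(x) != ncol(model$X))
    stop("feature dimension mismatch: model expects ", ncol(model$X))
  K <- svm_kernel(x, model$X, model$kernel, model$gamma, model$degree,
                  model$coef0)
  drop(K %*% (model$alpha * model$y) + model$b)
}

#' Classify with a trained SVM
#'
#' Returns +1 (contaminated) where the decision value is strictly
#' positive, -1 (normal) otherwise; a point exactly on the hyperplane is
#' called normal.
#'
#' @inheritParams svm_decision
#' @return Integer label(s) in \{-1, +1\}.
#' @export
svm_predict <- function(model, x) {
  ifelse(svm_decision(model, x) > 0, 1L, -1L)
}

#' @export
print.swell_svm <- function(x, ...) {
  cat("<swell_svm>", x$kernel, "kernel, C =", x$C, "-",
      sum(x$alpha > 1e-7 * x$C), "support vectors, objective",
      format(x$objective, digits = 6), "\n")
  invisible(x)
}

## Minimum volume ellipsoid -------------------------------------------------

#' Fit the minimum-volume enclosing ellipsoid (Khachiyan's algorithm)
#'
#' Finds the smallest ellipsoid \eqn{(x-c)^\top A (x-c) \le 1} containing
#' all training points, by minimizing \eqn{\log\det A^{-1}} subject to
#' containment. Khachiyan's algorithm starts from a large feasible
#' ellipsoid and shrinks it iteratively: each step moves weight toward the
#' point currently most outside the trial ellipsoid, until the weight
#' vector stabilizes. Used as a one-class (novelty) model: it is fitted on
#' normal data only, and anything outside the ellipsoid is flagged.
#'
#' @param P n x m matrix of training points (rows).
#' @param tolerance Convergence tolerance on the weight update, default
#'   \code{1e-7}.
#' @param max_iter Iteration cap, default \code{1e5}.
#' @return Object of class \code{swell_mve}: \code{center} c,
#'   \code{shape} A (symmetric positive definite), \code{tolerance},
#'   iteration count and a degeneracy flag. The ellipsoid is rescaled so
#'   the most extreme training point lies exactly on the boundary, hence
#'   containment of the training set is exact.
#' @export
mve_fit <- function(P, tolerance = 1e-7, max_iter = 1e5) {
  P <- as.matrix(P)
  n <- nrow(P); m <- ncol(P)
  stopifnot(n >= 1, m >= 1, tolerance > 0)
  Q <- t(cbind(P, 1))                      # lifted points, (m+1) x n
  d1 <- m + 1
  u <- rep(1 / n, n)
  X <- Q %*% (u * t(Q))
  Xinv <- tryCatch(solve(X), error = function(e) NULL)
  if (is.null(Xinv)) Xinv <- solve(X + diag(1e-10 * (sum(diag(X)) / d1 + 1), d1))
  M <- colSums(Q * (Xinv %*% Q))
  iter <- 0L
  repeat {
    iter <- iter + 1L
    j <- which.max(M)
    kappa <- M[j]
    step <- (kappa - d1) / (d1 * (kappa - 1))
    if (!is.finite(step) || step <= 0) break
    u_new <- (1 - step) * u
    u_new[j] <- u_new[j] + step
    delta <- sqrt(sum((u_new - u)^2))
    u <- u_new
    # rank-1 update of Xinv and the point scores M
    if (iter %% 500L == 0L) {
      X <- Q %*% (u * t(Q))
      Xinv <- solve(X + diag(1e-12 * sum(diag(X)) / d1, d1))
      M <- colSums(Q * (Xinv %*% Q))
    } else {
      qj <- Q[, j]
      v <- drop(crossprod(Q, Xinv %*% qj))   # q_i' Xinv q_j
      denom <- (1 - step) + step * kappa
      M <- (M - step * v^2 / denom) / (1 - step)
      Xinv <- (Xinv - (step / denom) * tcrossprod(Xinv %*% qj)) / (1 - step)
    }
    if (delta < tolerance || iter >= max_iter) break
  }
  center <- drop(crossprod(P, u))
  S <- crossprod(P, u * P) - tcrossprod(center)
  degenerate <- is.null(tryCatch(chol(S), error = function(e) NULL))
  if (degenerate) {
    warning("degenerate point set (rank < m); ridge regularization applied")
    S <- S + diag(1e-8 * (sum(diag(S)) / m + 1), m)
  }
  A <- solve(S) / m
  A <- (A + t(A)) / 2
  # rescale so every training point is inside, extreme point on boundary
  dif <- sweep(P, 2, center)
  q <- rowSums((dif %*% A) * dif)
  qmax <- max(q)
  if (qmax > 0) A <- A / qmax
  structure(list(center = center, shape = A, tolerance = tolerance,
                 iterations = iter, degenerate = degenerate,
                 weights = u),
            class = "swell_mve")
}

#' Mahalanobis-type ellipsoid distance
#'
#' @param model A \code{\link{mve_fit}} model.
#' @param x Point or matrix of points (rows).
#' @return \eqn{(x-c)^\top A (x-c)}; at most 1 inside the ellipsoid.
#' @export
mve_distance <- function(model, x) {
  x <- if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
  if (ncol(x) != length(model$center))
    stop("feature dimension mismatch: model expects ", length(model$center))
  dif <- sweep(x, 2, model$center)
  rowSums((dif %*% model$shape) * dif)
}

#' Classify points against a fitted ellipsoid
#'
#' A vector inside the ellipsoid (quadratic form at most
#' \code{1 + tolerance}) belongs to the modeled (normal) class; anything
#' outside is an outlier.
#'
#' @inheritParams mve_distance
#' @return Character vector, \code{"normal"} or \code{"outlier"}.
#' @export
mve_classify <- function(model, x) {
  ifelse(mve_distance(model, x) <= 1 + model$tolerance, "normal", "outlier")
}

#' Volume of a fitted ellipsoid
#'
#' @param model A \code{swell_mve}.
#' @return \eqn{V_m/\sqrt{\det A}} with \eqn{V_m} the unit-ball volume.
#' @export
mve_volume <- function(model) {
  m <- length(model$center)
  (pi^(m / 2) / gamma(m / 2 + 1)) / sqrt(det(model$shape))
}

#' @export
print.swell_mve <- function(x, ...) {
  cat("<swell_mve>", length(x$center), "dims,", x$iterations,
      "iterations, volume", format(mve_volume(x), digits = 4),
      if (x$degenerate) "(regularized)" else "", "\n")
  invisible(x)
}

## Delay-embedded neural baseline -------------------------------------------

delay_embed <- function(series, d) {
  T <- length(series)
  if (T <= d) stop("series too short for delay ", d)
  X <- sapply(seq_len(d), function(j) series[(d + 1 - j):(T - j)])
  list(X = matrix(X, ncol = d), y = series[(d + 1):T])
}

#' Grid-search a delay-embedded neural network baseline
#'
#' Fits one-hidden-layer networks predicting
#' \eqn{y(t) = f(y(t-1), \ldots, y(t-d))} for every combination of hidden
#' units \code{f} and delay \code{d}, and keeps the pair minimizing the
#' normalized mean squared error (nMSE = MSE / variance of the target) on
#' the training series. Training uses \pkg{nnet}'s quasi-Newton
#' optimizer with a fixed seed for weight initialization, so the search is
#' deterministic.
#'
#' @param series Numeric vector (daily counts or a reduced-coefficient
#'   trace).
#' @param f_range Candidate hidden-unit counts, default \code{1:8}.
#' @param d_range Candidate delays, default \code{1:14}.
#' @param seed Integer seed for weight initialization.
#' @param maxit Optimizer iteration cap per fit, default 300.
#' @return Object of class \code{swell_ann}: the winning \code{fit}
#'   (an \pkg{nnet} object), \code{f}, \code{d}, \code{nmse}, \code{seed}
#'   and the full search \code{grid}.
#' @export
ann_fit_grid <- function(series, f_range = 1:8, d_range = 1:14, seed = 1,
                         maxit = 300) {
  series <- as.numeric(series)
  d_range <- d_range[d_range < length(series) - 1]
  if (!length(d_range))
    stop("series too short for every requested delay")
  sc <- max(abs(series), 1)   # scale to a friendly optimizer range
  rows <- list(); best <- NULL
  for (d in d_range) {
    emb <- delay_embed(series / sc, d)
    vy <- stats::var(emb$y) * (length(emb$y) - 1) / length(emb$y)
    for (f in f_range) {
      fit <- with_seed(derive_seed(seed, f * 1000 + d),
        nnet::nnet(emb$X, emb$y, size = f, linout = TRUE, trace = FALSE,
                   maxit = maxit, decay = 1e-6))
      mse <- mean((emb$y - drop(fit$fitted.values))^2)
      nmse <- if (vy > 0) mse / vy else mse
      rows[[length(rows) + 1L]] <- data.frame(f = f, d = d, nmse = nmse)
      if (is.null(best) || nmse < best$nmse - 1e-12)
        best <- list(fit = fit, f = f, d = d, nmse = nmse)
    }
  }
  structure(list(fit = best$fit, f = best$f, d = best$d, nmse = best$nmse,
                 scale = sc, seed = seed, grid = do.call(rbind, rows)),
            class = "swell_ann")
}

#' Iterated forecasts from a delay network
#'
#' @param model A \code{\link{ann_fit_grid}} model.
#' @param recent Numeric history, length at least the model delay.
#' @param horizon Number of steps to forecast.
#' @return Numeric vector of \code{horizon} forecasts.
#' @export
ann_forecast <- function(model, recent, horizon = 1) {
  recent <- as.numeric(recent) / model$scale
  d <- model$d
  if (length(recent) < d)
    stop("need at least ", d, " recent values (the model delay)")
  out <- numeric(horizon)
  buf <- utils::tail(recent, d)
  for (h in seq_len(horizon)) {
    xin <- matrix(rev(buf), nrow = 1)   # (y(t-1), ..., y(t-d))
    pred <- drop(stats::predict(model$fit, xin))
    out[h] <- pred
    buf <- c(buf[-1], pred)
  }
  out * model$scale
}

#' Alarm decision from the neural baseline
#'
#' Iterates the delay network forward and throws an alarm when any
#' forecast within the horizon exceeds the event threshold -- i.e. when
#' the predicted near future would classify the upcoming window as
#' contaminated under the same exceedance rule used in training.
#'
#' @param model A \code{swell_ann}.
#' @param recent Numeric history (at least \code{model$d} values).
#' @param event_threshold Count threshold, default 10.
#' @param horizon Forecast horizon in steps, default 90.
#' @return \code{"alarm"} or \code{"none"}.
#' @export
ann_alarm <- function(model, recent, event_threshold = 10, horizon = 90) {
  fc <- ann_forecast(model, recent, horizon)
  if (any(fc > event_threshold)) "alarm" else "none"
}

#' @export
print.swell_ann <- function(x, ...) {
  cat("<swell_ann> f =", x$f, "hidden units, delay d =", x$d,
      "- training nMSE", format(x$nmse, digits = 4), "\n")
  invisible(x)
}
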