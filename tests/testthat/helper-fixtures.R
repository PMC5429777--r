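# Shared fixtures: all built in code at test time.

# A daily grid directly from a values vector (every day "observed").
grid_from_values <- function(values, start = as.Date("2001-01-01")) {
  structure(list(start_date = start, values = as.numeric(values),
                 observed = rep(TRUE, length(values)), well_id = "fix"),
            class = "daily_grid")
}

# A sparse grid: zeros except counts at given 0-based offsets.
sparse_grid <- function(n, offsets, counts) {
  v <- numeric(n)
  v[offsets + 1L] <- counts
  obs <- logical(n)
  obs[offsets + 1L] <- TRUE
  structure(list(start_date = as.Date("2001-01-01"), values = v,
                 observed = obs, well_id = "fix"),
            class = "daily_grid")
}

# Direct evaluation of the DCT sum, term by term (independent of dct_basis).
dct_reference <- function(x) {
  N <- length(x)
  vapply(0:(N - 1), function(k)
    sum(x * cos(pi / N * ((0:(N - 1)) + 0.5) * k)), numeric(1))
}

# Brute-force minimal-area enclosing ellipse via a dense parameter grid:
# centers x angles x axis ratios; for each, the smallest ellipse of that
# shape containing the points. Returns the best area found.
ellipse_grid_oracle <- function(P, n_center = 7, n_theta = 12, n_ratio = 12) {
  cx <- seq(min(P[, 1]), max(P[, 1]), length.out = n_center)
  cy <- seq(min(P[, 2]), max(P[, 2]), length.out = n_center)
  thetas <- seq(0, pi, length.out = n_theta + 1)[-(n_theta + 1)]
  ratios <- exp(seq(log(0.2), log(5), length.out = n_ratio))
  best <- Inf
  for (x0 in cx) for (y0 in cy) for (th in thetas) {
    u <- cbind(P[, 1] - x0, P[, 2] - y0) %*%
      cbind(c(cos(th), sin(th)), c(-sin(th), cos(th)))
    for (r in ratios) {
      a2 <- max(u[, 1]^2 + (u[, 2] / r)^2)   # minimal a for this shape
      area <- pi * a2 * r
      if (area < best) best <- area
    }
  }
  best
}

# Reference primal SVM objective from any (w, b): 0.5||w||^2 + C sum(slack).
# With optimize_b the intercept is chosen optimally for this w (the hinge
# total is piecewise linear in b, so its optimum sits at a kink).
svm_primal_objective <- function(w, b, X, y, C, optimize_b = FALSE) {
  f0 <- drop(X %*% w)
  obj <- function(bb) 0.5 * sum(w^2) + C * sum(pmax(0, 1 - y * (f0 + bb)))
  if (!optimize_b) return(obj(b))
  min(vapply(c(b, y - f0), obj, numeric(1)))
}

# Exhaustive hard-margin oracle for small separable 2-d sets: enumerate
# candidate active sets (one pair across classes, or triples), solve for
# (w, b), keep the feasible hyperplane with minimal ||w||.
hard_margin_oracle <- function(X, y) {
  n <- nrow(X)
  best <- NULL
  consider <- function(w, b) {
    if (any(!is.finite(c(w, b)))) return()
    if (all(y * (drop(X %*% w) + b) >= 1 - 1e-9)) {
      if (is.null(best) || sum(w^2) < sum(best$w^2) - 1e-12)
        best <<- list(w = w, b = b)
    }
  }
  for (i in 1:n) for (j in 1:n) {
    if (y[i] == 1 && y[j] == -1) {
      d <- X[i, ] - X[j, ]
      w <- 2 * d / sum(d^2)
      b <- 1 - sum(w * X[i, ])
      consider(w, b)
    }
  }
  for (i in 1:n) for (j in 1:n) for (k in 1:n) {
    if (i < j && length(unique(y[c(i, j, k)])) == 2 && k != i && k != j) {
      A <- cbind(X[c(i, j, k), , drop = FALSE], 1)
      rhs <- y[c(i, j, k)]
      sol <- tryCatch(solve(A, rhs), error = function(e) NULL)
      if (!is.null(sol)) consider(sol[1:2], sol[3])
    }
  }
  best
}
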