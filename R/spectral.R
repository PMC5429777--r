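# Basis cache: the N-point cosine matrix is reused by every window of a run.
.dct_cache <- new.env(parent = emptyenv())

#' Cosine basis matrix of the unnormalized type-II DCT
#'
#' Returns the N x N matrix \code{C} with
#' \code{C[k+1, n+1] = cos(pi/N * (n + 1/2) * k)}, so the forward transform
#' is \code{X = C \%*\% x}. Rows are mutually orthogonal with squared norm
#' \code{N} (k = 0) or \code{N/2} (k > 0); no normalization is applied on
#' the forward side.
#'
#' @param n Signal length N.
#' @return N x N numeric matrix.
#' @export
dct_basis <- function(n) {
  stopifnot(n >= 1)
  key <- as.character(n)
  if (!is.null(.dct_cache[[key]])) return(.dct_cache[[key]])
  k <- 0:(n - 1)
  C <- cos(outer(k, (k + 0.5) * pi / n))
  .dct_cache[[key]] <- C
  C
}

#' Forward DCT of a time window
#'
#' Computes \code{X_k = sum_n x_n cos(pi/N (n + 1/2) k)}, k = 0..N-1: the
#' unnormalized type-II discrete cosine transform. Because each time sample
#' contributes an additive term to every coefficient, days holding
#' fictitious zeroes drop out of the sums entirely -- the justification for
#' zero-filling unsampled days.
#'
#' @param values Numeric vector of length N (a time-domain window).
#' @return Numeric vector of N DCT coefficients.
#' @export
dct_forward <- function(values) {
  if (length(values) < 1L) stop("empty window")
  drop(dct_basis(length(values)) %*% as.numeric(values))
}

#' Inverse DCT
#'
#' Exact inverse of \code{\link{dct_forward}}: since the forward rows are
#' orthogonal, \code{x = t(C) \%*\% (X * w)} with weights \code{w = 1/N}
#' for k = 0 and \code{2/N} otherwise.
#'
#' @param coefficients Numeric vector of DCT coefficients.
#' @return The reconstructed time-domain vector.
#' @export
dct_inverse <- function(coefficients) {
  n <- length(coefficients)
  if (n < 1L) stop("empty spectrum")
  w <- c(1 / n, rep(2 / n, n - 1L))
  drop(crossprod(dct_basis(n), as.numeric(coefficients) * w))
}

#' Verify the per-sample (zero-contribution) decomposition
#'
#' Checks that the DCT of a window equals the sum, over its non-zero
#' entries only, of count times basis column -- i.e. that zero entries
#' contribute nothing. This is the formal content of the fictitious-zero
#' argument and is exposed as a test utility.
#'
#' @param values Time-domain window.
#' @param zero_positions 0-based positions asserted to be zero.
#' @param tol Absolute tolerance, default \code{1e-9}.
#' @return \code{TRUE} or \code{FALSE}.
#' @export
zero_contribution_check <- function(values, zero_positions,
                                    tol = 1e-9) {
  n <- length(values)
  if (length(zero_positions) &&
      any(values[zero_positions + 1L] != 0))
    stop("claimed zero positions hold non-zero values")
  full <- dct_forward(values)
  C <- dct_basis(n)
  nz <- setdiff(which(values != 0), zero_positions + 1L)
  partial <- if (length(nz)) drop(C[, nz, drop = FALSE] %*% values[nz])
             else numeric(n)
  max(abs(full - partial)) < tol
}

#' Draw a fixed random subset of DCT coefficient indices
#'
#' Dimension reduction keeps \code{m} of the N coefficients; the same
#' (randomly chosen) index set is applied to every window of a run, so the
#' selection is drawn once, from a recorded seed.
#'
#' @param window_length N, the window length.
#' @param n_coeffs m, number of coefficients to keep (1..N).
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @param include_dc Force inclusion of the k = 0 (DC) coefficient;
#'   off by default -- the selection is arbitrary by design.
#' @return Object of class \code{coefficient_selection}: sorted 0-based
#'   \code{indices} and the \code{seed}.
#' @export
select_coefficients <- function(window_length, n_coeffs, seed,
                                include_dc = FALSE) {
  if (n_coeffs < 1 || n_coeffs > window_length)
    stop("n_coeffs must lie in [1, window_length]")
  idx <- with_seed(seed, sample.int(window_length, n_coeffs)) - 1L
  if (include_dc && !0L %in% idx) idx[1L] <- 0L
  structure(list(indices = sort(idx), seed = seed),
            class = "coefficient_selection")
}

#' Reduce a spectrum to the selected coefficients
#'
#' @param coefficients Full DCT coefficient vector.
#' @param selection A \code{\link{select_coefficients}} result.
#' @return Numeric vector of length m, coefficients in index order.
#' @export
reduce_window <- function(coefficients, selection) {
  idx <- selection$indices
  if (any(idx < 0) || any(idx >= length(coefficients)))
    stop("selection index out of range for this window length")
  coefficients[idx + 1L]
}

#' Sliding-window DCT spectra of a daily grid
#'
#' Transforms every window position of the grid. \code{mode = "direct"}
#' recomputes each window from scratch; \code{mode = "incremental"} keeps a
#' running set of the non-zero samples inside the window, updating it as
#' the window slides (one sample enters, one leaves) and summing basis
#' columns over that active set only. On sparse count grids the
#' incremental path does a small fraction of the direct work and agrees
#' with it to floating-point accuracy.
#'
#' @param grid A \code{daily_grid} (or plain numeric vector).
#' @param window_days Window length, default 90.
#' @param stride Step between window starts, default 1.
#' @param mode \code{"direct"} or \code{"incremental"}.
#' @return List with \code{starts} (0-based) and \code{coefficients}
#'   (matrix, one row per window position).
#' @export
sliding_spectra <- function(grid, window_days = 90, stride = 1,
                            mode = c("direct", "incremental")) {
  mode <- match.arg(mode)
  values <- if (inherits(grid, "daily_grid")) grid$values else as.numeric(grid)
  n <- length(values)
  if (window_days > n) stop("window longer than grid")
  starts <- seq.int(0L, n - window_days, by = stride)
  C <- dct_basis(window_days)
  if (mode == "direct") {
    coef <- t(vapply(starts, function(s)
      drop(C %*% values[(s + 1L):(s + window_days)]), numeric(window_days)))
  } else {
    nz <- which(values != 0)   # global 1-based positions of non-zero samples
    coef <- matrix(0, length(starts), window_days)
    lo <- 1L; hi <- 0L
    for (r in seq_along(starts)) {
      s <- starts[r]
      while (hi < length(nz) && nz[hi + 1L] <= s + window_days) hi <- hi + 1L
      while (lo <= length(nz) && nz[lo] <= s) lo <- lo + 1L
      if (lo <= hi) {
        act <- nz[lo:hi]
        coef[r, ] <- drop(C[, act - s, drop = FALSE] %*% values[act])
      }
    }
  }
  list(starts = starts, coefficients = coef)
}

#' Reconstruct a sparse signal from partial DCT measurements (basis pursuit)
#'
#' Solves \eqn{(P_1)\;\min \|x\|_1 \ \mathrm{s.t.}\ Ax = b}, where the rows
#' of A are rows of the N-point unnormalized DCT matrix, selected by
#' \code{rows}, and \code{b} holds the observed coefficients. A
#' sufficiently sparse signal is recovered exactly from a small fraction of
#' its spectral coefficients.
#'
#' Two solvers are provided. \code{"lp"} states the problem as the standard
#' linear program (x = u - v, u, v >= 0, minimize sum(u + v)) and is exact
#' on small instances. \code{"admm"} is a scaled first-order splitting
#' method that alternates projection onto \{Ax = b\} (cheap here: the DCT
#' rows are orthogonal, so A A' is diagonal) with soft thresholding, then
#' polishes by least squares on the detected support; it scales to
#' thousands of variables. \code{"auto"} picks \code{"lp"} for
#' \code{signal_length <= 128}, else \code{"admm"}.
#'
#' @param measured Numeric vector b of observed DCT coefficients.
#' @param rows 0-based DCT row indices (the k's that were measured).
#' @param signal_length n, the length of the unknown signal.
#' @param method \code{"auto"}, \code{"lp"} or \code{"admm"}.
#' @param tol Feasibility tolerance on \code{max|Ax - b|}; default
#'   \code{1e-8}.
#' @param max_iter Iteration cap for the ADMM solver.
#' @return Numeric vector x of length n with \code{max|Ax - b| < tol}.
#' @export
basis_pursuit <- function(measured, rows, signal_length,
                          method = c("auto", "lp", "admm"),
                          tol = 1e-8, max_iter = 50000L) {
  method <- match.arg(method)
  m <- length(measured)
  if (m < 1L) stop("no measurements")
  if (length(rows) != m) stop("rows and measured differ in length")
  if (any(rows < 0) || any(rows >= signal_length)) stop("row index out of range")
  if (anyDuplicated(rows)) stop("duplicate measurement rows")
  n <- as.integer(signal_length)
  A <- dct_basis(n)[rows + 1L, , drop = FALSE]
  b <- as.numeric(measured)
  if (method == "auto") method <- if (n <= 128L) "lp" else "admm"
  x <- if (m == n) {
    # fully determined: every coefficient observed, invert directly
    full <- numeric(n); full[rows + 1L] <- b
    dct_inverse(full)
  } else if (method == "lp") {
    .bp_lp(A, b, n)
  } else {
    .bp_admm(A, b, n, tol = tol, max_iter = max_iter)
  }
  resid <- max(abs(A %*% x - b))
  if (resid >= tol)
    stop("basis pursuit did not reach feasibility (residual ",
         format(resid), "); the system may be inconsistent")
  x
}

# LP route: min 1'(u+v) s.t. [A -A][u;v] = b, u,v >= 0. Rows are scaled to
# unit norm first (pure row scaling; keeps the simplex well conditioned).
.bp_lp <- function(A, b, n) {
  rn <- sqrt(rowSums(A^2)); rn[rn == 0] <- 1
  sol <- pracma::linprog(cc = rep(1, 2 * n), Aeq = cbind(A / rn, -A / rn),
                         beq = b / rn, maxiter = 200 * n)
  if (is.null(sol$x)) stop("LP solver failed on basis pursuit instance")
  sol$x[1:n] - sol$x[(n + 1):(2 * n)]
}

# Splitting method with diagonal A A' (orthogonal DCT rows), plus
# least-squares debiasing on the detected support.
.bp_admm <- function(A, b, n, tol = 1e-8, max_iter = 50000L, rho = NULL) {
  d <- rowSums(A^2)                      # A A' is diag(d)
  At_Dinv_b <- drop(crossprod(A, b / d))
  proj <- function(v) v - drop(crossprod(A, drop(A %*% v) / d)) + At_Dinv_b
  if (is.null(rho)) rho <- 1 / max(abs(At_Dinv_b), 1e-12)
  lam <- 1 / rho
  z <- proj(numeric(n)); u <- numeric(n)
  soft <- function(v, t) sign(v) * pmax(abs(v) - t, 0)
  best <- NULL
  for (it in seq_len(max_iter)) {
    x <- proj(z - u)
    z_old <- z
    z <- soft(x + u, lam)
    u <- u + x - z
    if (it %% 100L == 0L || it == max_iter) {
      # debias: least squares on the active support, accept if feasible
      supp <- which(abs(z) > 1e-6 * max(abs(z), 1))
      if (length(supp) >= 1L && length(supp) <= nrow(A)) {
        As <- A[, supp, drop = FALSE]
        cand <- tryCatch(qr.solve(As, b), error = function(e) NULL)
        if (!is.null(cand)) {
          xc <- numeric(n); xc[supp] <- cand
          if (max(abs(As %*% cand - b)) < tol) {
            if (is.null(best) || sum(abs(xc)) < sum(abs(best))) best <- xc
            # stop once the splitting iterate agrees with the polished point
            if (max(abs(z - xc)) < 1e-6 && max(abs(z - z_old)) < 1e-9) break
          }
        }
      }
      if (max(abs(x - z)) < 1e-12 && max(abs(z - z_old)) < 1e-12) break
    }
  }
  xf <- proj(z)  # feasible point closest to the sparse iterate
  if (!is.null(best) && sum(abs(best)) <= sum(abs(xf)) + 1e-9) best else xf
}
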