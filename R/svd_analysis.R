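#' Singular value decomposition of a difference-curve matrix
#'
#' Exact SVD of the q x delay matrix. Left singular vectors (lSVs) are
#' q-space basis patterns; right singular vectors (rSVs) are their time
#' courses. The number of structurally distinct intermediates shows up as
#' the number of significant components (see [count_significant()]).
#'
#' @param mat a `trxss_diffmat`
#' @return object of class `trxss_svd`: list with `u`, `d`, `v`, the
#'   input `q` and `delays`, and `n_significant` (NA until
#'   [count_significant()] is applied)
#' @export
svd_decompose <- function(mat) {
  stopifnot(inherits(mat, "trxss_diffmat"))
  if (any(!is.finite(mat$values))) stop("matrix contains non-finite entries")
  s <- svd(mat$values)
  out <- list(u = s$u, d = s$d, v = s$v, q = mat$q, delays = mat$delays,
              n_significant = NA_integer_)
  class(out) <- "trxss_svd"
  out
}

#' @export
print.trxss_svd <- function(x, ...) {
  cat(sprintf("<trxss_svd> %d x %d, leading singular values: %s\n",
              nrow(x$u), nrow(x$v),
              paste(signif(head(x$d, 5), 3), collapse = ", ")))
  if (!is.na(x$n_significant)) {
    cat(sprintf("  %d significant component(s)\n", x$n_significant))
  }
  invisible(x)
}

lag1_autocor <- function(v) {
  n <- length(v)
  num <- sum(v[-1] * v[-n])
  den <- sum(v^2)
  if (den == 0) return(0)
  num / den
}

#' Count significant SVD components
#'
#' A component k is significant when both hold: its singular value exceeds
#' `magnitude_factor` times the median of the trailing half of the
#' singular values (a noise-floor estimate), and the lag-1 autocorrelation
#' of both its lSV and its rSV exceeds `autocor_min` (signal vectors are
#' smooth, noise vectors are not). The count is the largest k such that
#' components 1..k all pass. With fewer than 4 components the
#' autocorrelation test is skipped and only the magnitude test applies.
#'
#' @param svd a `trxss_svd`
#' @param magnitude_factor multiple of the noise-floor estimate (default 3)
#' @param autocor_min autocorrelation threshold (default 0.8)
#' @return the input `trxss_svd` with `n_significant` set; access the
#'   count directly via `$n_significant` or take `as.integer()` of it
#' @export
count_significant <- function(svd, magnitude_factor = 3, autocor_min = 0.8) {
  stopifnot(inherits(svd, "trxss_svd"))
  d <- svd$d
  n <- length(d)
  trailing <- if (n >= 2) d[seq(ceiling(n / 2) + 1, n)] else d
  floor_est <- median(trailing)
  pass_mag <- d > magnitude_factor * floor_est
  if (n < 4L) {
    pass <- pass_mag
  } else {
    pass_ac <- vapply(seq_len(n), function(k) {
      lag1_autocor(svd$u[, k]) > autocor_min &&
        lag1_autocor(svd$v[, k]) > autocor_min
    }, logical(1))
    pass <- pass_mag & pass_ac
  }
  k <- if (all(pass)) n else which(!pass)[1] - 1L
  svd$n_significant <- as.integer(k)
  svd
}

#' Global multi-exponential fit of right singular vectors
#'
#' Fits all supplied rSVs simultaneously with a sum of `n_exp`
#' exponentials sharing one set of time constants:
#' v_j(t) = c_j + sum_i a_ij exp(-t / tau_i). Amplitudes and offsets are
#' solved linearly at each step of the nonlinear search over the time
#' constants (variable projection), which removes the usual local-minimum
#' trap; the nonlinear search is multi-started from log-uniform random
#' time-constant sets.
#'
#' This fit is purely descriptive: it reports the relaxation rates visible
#' in the data without committing to a kinetic scheme.
#'
#' @param rsv matrix of right singular vectors (delays in rows, one vector
#'   per column), or a `trxss_svd` (its first `n_vectors` rSVs are used)
#' @param delays time delays in seconds
#' @param n_exp number of exponentials (>= 1, < number of delays)
#' @param weights per-vector weights (default: the singular values when a
#'   `trxss_svd` is supplied, so dominant kinetics are emphasised;
#'   otherwise 1)
#' @param n_vectors number of rSVs used when `rsv` is a `trxss_svd`
#' @param n_starts multi-start count (default 32)
#' @param tau_range log-uniform sampling range for initial time constants
#'   (default 10 ps to 100 ms)
#' @param seed RNG seed for the multi-start draws
#' @return object of class `multiexp_fit`: list with `tau` (sorted
#'   ascending), `amplitudes` (n_exp x n_vectors), `offsets`,
#'   `residual` (weighted residual norm), `converged`
#' @export
fit_multiexponential <- function(rsv, delays, n_exp, weights = NULL,
                                 n_vectors = 3, n_starts = 32,
                                 tau_range = c(1e-11, 0.1), seed = 1) {
  if (inherits(rsv, "trxss_svd")) {
    if (is.null(weights)) weights <- rsv$d[seq_len(n_vectors)]
    delays <- rsv$delays
    rsv <- rsv$v[, seq_len(n_vectors), drop = FALSE]
  }
  rsv <- as.matrix(rsv)
  stopifnot(n_exp >= 1, all(delays > 0))
  if (n_exp >= length(delays)) stop("n_exp must be < number of delays")
  if (is.null(weights)) weights <- rep(1, ncol(rsv))
  W <- matrix(weights, nrow(rsv), ncol(rsv), byrow = TRUE)

  # the nonlinear parameters are log-rates r = -log(tau); the decay
  # columns are exp(-t * exp(r)), and tau = exp(-r) on the way out.
  # The linear subproblem is solved through lightly ridged normal
  # equations: duplicate or dead exponential columns then cost residual
  # instead of erroring, which keeps the nonlinear search smooth.
  design <- function(ltau) cbind(1, exp(-outer(delays, exp(ltau))))
  resid_fun <- function(ltau) {
    X <- design(ltau)
    G <- crossprod(X)
    fit <- tryCatch(
      solve(G + 1e-10 * mean(diag(G)) * diag(nrow(G)), crossprod(X, rsv)),
      error = function(e) NULL)
    if (is.null(fit)) return(list(value = 1e30))
    R <- rsv - X %*% fit
    list(value = sum((R * W)^2), coef = fit)
  }
  obj <- function(ltau) resid_fun(ltau)$value

  set.seed(seed)
  lo <- -log(tau_range[2])
  hi <- -log(tau_range[1])
  fit_one <- function() {
    # narrow basin: bracket by a coarse grid scan, then local search
    grid <- seq(lo, hi, length.out = 400)
    k <- which.min(vapply(grid, obj, numeric(1)))
    o <- stats::optimize(obj, grid[c(max(1, k - 1),
                                     min(length(grid), k + 1))],
                         tol = 1e-12)
    list(par = o$minimum, value = o$objective, convergence = 0)
  }
  # greedy build-up: the k-exponential search is warm-started from the
  # (k-1)-exponential solution plus one extra constant, alongside random
  # multi-starts; this makes the residual non-increasing in n_exp and
  # avoids the local traps of a cold high-dimensional search
  best <- NULL
  for (k in seq_len(n_exp)) {
    if (k == 1L) {
      best <- fit_one()
      next
    }
    starts <- lapply(seq_len(max(3, ceiling(n_starts / 4))), function(i) {
      sort(c(best$par, runif(1, lo, hi)))
    })
    starts <- c(starts,
                lapply(seq_len(n_starts - length(starts)), function(i) {
                  sort(runif(k, lo, hi))
                }))
    cand <- NULL
    for (st in starts) {
      fit <- optim(st, obj, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-13))
      if (is.null(cand) || fit$value < cand$value) cand <- fit
    }
    cand <- optim(cand$par, obj, method = "Nelder-Mead",
                  control = list(maxit = 5000, reltol = 1e-15))
    # a warm start can only improve on the previous residual; keep the
    # better of the two so the sequence is monotone by construction
    best <- if (cand$value <= best$value) cand else
      list(par = sort(c(best$par, hi)), value = best$value,
           convergence = 0)
  }
  rf <- resid_fun(best$par)
  tau <- exp(-best$par)

  ord <- order(tau)
  out <- list(tau = tau[ord],
              amplitudes = rf$coef[-1, , drop = FALSE][ord, , drop = FALSE],
              offsets = rf$coef[1, ],
              residual = rf$value,
              converged = best$convergence == 0 || best$value < 1e29)
  class(out) <- "multiexp_fit"
  out
}

#' @export
print.multiexp_fit <- function(x, ...) {
  cat("<multiexp_fit> time constants:",
      paste(sprintf("%.3g s", x$tau), collapse = ", "), "\n")
  cat(sprintf("  weighted residual: %.4g\n", x$residual))
  invisible(x)
}

#' Remove a solvent-heating component from a difference matrix
#'
#' For each time delay the ordinary least-squares projection of the
#' column onto the heating basis curve H(q) is subtracted:
#' column - alpha(t) H where alpha(t) = <column, H> / <H, H>. This is a
#' basis-projection simplification of full thermal-signal treatment and
#' is exact when the heating signature is proportional to a single known
#' basis curve.
#'
#' @param mat a `trxss_diffmat`
#' @param basis heating basis: a `trxss_curve` on the same q grid, or a
#'   numeric vector
#' @return list with `matrix` (corrected `trxss_diffmat`) and `alpha`
#'   (per-delay projection coefficients)
#' @export
remove_heating <- function(mat, basis) {
  h <- if (inherits(basis, "trxss_curve")) {
    if (length(basis$q) != length(mat$q) ||
        any(abs(basis$q - mat$q) > 1e-12)) stop("basis on a different q grid")
    basis$intensity
  } else as.numeric(basis)
  if (length(h) != length(mat$q)) stop("basis length mismatch")
  nh <- sum(h^2)
  if (nh == 0) stop("zero-norm heating basis")
  alpha <- as.numeric(crossprod(h, mat$values)) / nh
  cleaned <- mat$values - outer(h, alpha)
  list(matrix = difference_matrix(mat$q, mat$delays, cleaned,
                                  sigma = mat$sigma),
       alpha = alpha)
}
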