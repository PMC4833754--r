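test_that("svd_decompose is exact on low-rank constructions", {
  q <- seq(0.2, 0.9, length.out = 40)
  delays <- 10^seq(-9, -3, length.out = 12)
  u <- sin(5 * q)
  v <- exp(-delays / 1e-6)
  m1 <- difference_matrix(q, delays, outer(u, v))
  s1 <- svd_decompose(m1)
  expect_equal(sum(s1$d > 1e-10 * s1$d[1]), 1L)

  set.seed(4)
  U <- qr.Q(qr(matrix(rnorm(40 * 3), 40)))
  V <- qr.Q(qr(matrix(rnorm(12 * 3), 12)))
  m3 <- difference_matrix(q, delays, U %*% diag(c(5, 2, 1)) %*% t(V))
  s3 <- svd_decompose(m3)
  expect_equal(sum(s3$d > 1e-10 * s3$d[1]), 3L)
  expect_lt(norm(crossprod(s3$u) - diag(12), "M"), 1e-10)
  expect_lt(norm(crossprod(s3$v) - diag(12), "M"), 1e-10)
  # reconstruction
  expect_equal(s3$u %*% diag(s3$d) %*% t(s3$v), m3$values, tolerance = 1e-8)
  m3$values[1, 1] <- NaN
  expect_error(svd_decompose(m3), "finite")
})

test_that("count_significant finds 3 on near-rank-3 data, 0 on white noise, and is scale invariant", {
  q <- seq(0.2, 0.9, length.out = 60)
  delays <- 10^seq(-9, -3, length.out = 20)
  set.seed(9)
  # smooth rank-3 signal plus tiny jitter
  U <- vapply(1:3, function(k) sin(k * 4 * q), numeric(length(q)))
  V <- vapply(c(1e-7, 1e-5, 1e-4), function(tau) exp(-delays / tau),
              numeric(length(delays)))
  vals <- U %*% diag(c(5, 2, 1)) %*% t(V)
  vals <- vals + matrix(rnorm(length(vals), 0, 1e-4 * max(abs(vals))),
                        nrow(vals))
  sv <- count_significant(svd_decompose(difference_matrix(q, delays, vals)))
  expect_equal(sv$n_significant, 3L)
  # positive rescaling cannot change the count
  sv2 <- count_significant(svd_decompose(
    difference_matrix(q, delays, 17.3 * vals)))
  expect_equal(sv2$n_significant, 3L)

  # pure white noise: modal count over replicates is 0
  counts <- vapply(1:50, function(i) {
    set.seed(1000 + i)
    nm <- difference_matrix(q, delays,
                            matrix(rnorm(length(q) * length(delays)),
                                   length(q)))
    count_significant(svd_decompose(nm))$n_significant
  }, integer(1))
  expect_equal(as.integer(names(which.max(table(counts)))), 0L)
})

test_that("retained components account for the variance implied by their singular values", {
  sim <- simulate_dataset(seed = 2)
  sv <- count_significant(svd_decompose(sim$matrix))
  k <- sv$n_significant
  recon <- sv$u[, 1:k] %*% diag(sv$d[1:k]) %*% t(sv$v[, 1:k])
  explained <- 1 - sum((sim$matrix$values - recon)^2) /
    sum(sim$matrix$values^2)
  expect_equal(explained, sum(sv$d[1:k]^2) / sum(sv$d^2), tolerance = 1e-10)
})

test_that("multi-exponential fit recovers time constants from clean and shared-tau data", {
  delays <- default_delays()
  # single exponential, noise-free: tau to 0.1%
  v <- exp(-delays / 1e-7)
  fit1 <- fit_multiexponential(matrix(v, ncol = 1), delays, n_exp = 1)
  expect_equal(fit1$tau, 1e-7, tolerance = 1e-3)

  # two vectors sharing tau = {1 ns, 1 us}: both within 1%
  X <- cbind(exp(-delays / 1e-9), exp(-delays / 1e-6))
  V2 <- cbind(X %*% c(1, 0.5), X %*% c(0.2, -1))
  fit2 <- fit_multiexponential(V2, delays, n_exp = 2, seed = 3)
  expect_equal(fit2$tau, c(1e-9, 1e-6), tolerance = 1e-2)
  expect_error(fit_multiexponential(V2, delays, n_exp = 40), "delays")
})

test_that("multi-exponential residual is non-increasing in the number of exponentials", {
  sim <- simulate_dataset(seed = 3)
  sv <- count_significant(svd_decompose(sim$matrix))
  res <- vapply(1:4, function(k) {
    fit_multiexponential(sv, delays = NULL, n_exp = k, n_starts = 8,
                         seed = 5)$residual
  }, numeric(1))
  expect_true(all(diff(res) <= 1e-8 * res[1]))
})

test_that("seven-exponential fit of the default dataset brackets the generative constants", {
  sim <- simulate_dataset(seed = 1)
  sv <- count_significant(svd_decompose(sim$matrix))
  fit <- fit_multiexponential(sv, delays = NULL, n_exp = 7, seed = 1)
  tau <- fit$tau
  # well-determined generative constants recovered within their printed
  # uncertainties (the two slowest fitted constants are descriptive
  # stand-ins for the non-exponential bimolecular phase)
  near <- function(truth, tol) expect_true(any(abs(tau - truth) <= tol))
  near(3.1e-9, 0.4e-9)
  near(140e-9, 80e-9)
  near(39e-6, 20e-6)
})

test_that("heating removal projects out the thermal component", {
  q <- default_qgrid()
  delays <- 10^seq(-9, -3, length.out = 10)
  H <- heating_basis(q)
  # matrix proportional to the basis at every delay -> all-zero output
  m <- difference_matrix(q, delays, outer(H$intensity, rep(2, 10)))
  out <- remove_heating(m, H)
  expect_equal(max(abs(out$matrix$values)), 0, tolerance = 1e-12)
  expect_equal(out$alpha, rep(2, 10))

  # orthogonal matrix passes through unchanged
  g <- sin(20 * q)
  g <- g - H$intensity * sum(g * H$intensity) / sum(H$intensity^2)
  m2 <- difference_matrix(q, delays, outer(g, seq_len(10)))
  out2 <- remove_heating(m2, H)
  expect_equal(out2$matrix$values, m2$values, tolerance = 1e-10)
  expect_error(remove_heating(m2, scattering_curve(q, rep(0, length(q)))),
               "zero-norm")
})

test_that("known heating amplitudes are recovered from noisy synthetic data", {
  # heating-only dataset (zero species curves) at the default 2% noise:
  # the per-delay projection coefficients must come back within 2% of
  # the generative amplitude profile
  q <- default_qgrid()
  zero <- scattering_curve(q, rep(0, length(q)))
  sim <- simulate_dataset(seed = 4, heating_amplitude = 1,
                          basis_curves = list(I1 = zero, I2 = zero,
                                              I3 = zero))
  out <- remove_heating(sim$matrix, heating_basis(q))
  truth <- sim$truth$heating_alpha
  expect_lt(max(abs(out$alpha - truth)) / max(truth), 0.02)
})
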