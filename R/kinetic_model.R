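#' Kinetic parameters of the HbI photocycle
#'
#' Parameter container for the branched photocycle: photolysis produces
#' fully and partially photolyzed I1; I1 relaxes to I2 (`tau12`); I2
#' branches with fixed fraction `f_gem` into a geminate-recombination
#' channel (`tau_gem`, producing ligated I1 which recovers the ground
#' state with `tau_lig`) and an R-T channel decaying to the T-like I3
#' biphasically (`tau_rt1` for the fully, `tau_rt2` for the partially
#' photolyzed substate); I3 rebinds solvent CO bimolecularly (`k_bi`).
#'
#' Defaults are the fitted values for the T72V mutant, which double as the
#' generative parameter set of [simulate_dataset()].
#'
#' @param tau12 I1-to-I2 time constant (s)
#' @param tau_gem geminate recombination time constant (s)
#' @param tau_rt1,tau_rt2 faster/slower R-T transition time constants (s);
#'   stored sorted so that `tau_rt1 <= tau_rt2`
#' @param tau_lig time constant for ligated I1 returning to the ground
#'   state (s)
#' @param k_bi bimolecular CO recombination rate constant (1/(mM s))
#' @param f_gem geminate branch fraction in `[0, 1]`
#' @param phi_full fraction of photolyzed molecules that are fully
#'   photolyzed, in `[0, 1]`
#' @param P0 photolyzed protein concentration (mM)
#' @param CO_excess initially free dissolved CO (mM)
#' @return object of class `kinetic_params` (named list)
#' @export
kinetic_params <- function(tau12 = 3.1e-9, tau_gem = 140e-9,
                           tau_rt1 = 490e-9, tau_rt2 = 980e-9,
                           tau_lig = 39e-6, k_bi = 310,
                           f_gem = 0.26, phi_full = 0.82,
                           P0 = 1, CO_excess = 1) {
  taus <- c(tau12 = tau12, tau_gem = tau_gem, tau_rt1 = tau_rt1,
            tau_rt2 = tau_rt2, tau_lig = tau_lig)
  if (any(taus <= 0)) stop("all time constants must be positive")
  if (k_bi < 0) stop("k_bi must be non-negative")
  if (f_gem < 0 || f_gem > 1) stop("f_gem must lie in [0, 1]")
  if (phi_full < 0 || phi_full > 1) stop("phi_full must lie in [0, 1]")
  rt <- sort(c(tau_rt1, tau_rt2))
  out <- list(tau12 = tau12, tau_gem = tau_gem,
              tau_rt1 = rt[1], tau_rt2 = rt[2], tau_lig = tau_lig,
              k_bi = k_bi, f_gem = f_gem, phi_full = phi_full,
              P0 = P0, CO_excess = CO_excess)
  class(out) <- "kinetic_params"
  out
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("<kinetic_params>\n")
  cat(sprintf("  tau12   = %.4g ns\n", x$tau12 * 1e9))
  cat(sprintf("  tau_gem = %.4g ns\n", x$tau_gem * 1e9))
  cat(sprintf("  tau_RT1 = %.4g ns   tau_RT2 = %.4g ns\n",
              x$tau_rt1 * 1e9, x$tau_rt2 * 1e9))
  cat(sprintf("  tau_lig = %.4g us\n", x$tau_lig * 1e6))
  cat(sprintf("  k_bi    = %.4g mM^-1 s^-1\n", x$k_bi))
  cat(sprintf("  f_gem   = %.3g  phi_full = %.3g\n", x$f_gem, x$phi_full))
  cat(sprintf("  P0 = %.3g mM  CO_excess = %.3g mM\n", x$P0, x$CO_excess))
  invisible(x)
}

.state_names <- c("I1_full", "I1_part", "I2_full_gem", "I2_full_rt",
                  "I2_part_gem", "I2_part_rt", "I1_lig", "I3_full",
                  "I3_part", "G", "CO")

#' Solve the photocycle populations over time
#'
#' Integrates the 11-state rate equations (stiff solver, compiled
#' right-hand side) from photolysis at t = 0 to the requested delays.
#' Initial condition: `I1_full = phi_full * P0`,
#' `I1_part = (1 - phi_full) * P0`, `CO = CO_excess`. CO escapes to the
#' free pool at the I2 -> I3 event (2 per fully, 1 per partially
#' photolyzed molecule) and is consumed with the same stoichiometry by
#' bimolecular recovery; geminate CO never leaves the protein.
#'
#' @param params a [kinetic_params()] object
#' @param delays output times in seconds (positive, increasing)
#' @param rtol,atol solver tolerances; the defaults keep protein and CO
#'   conservation below 1e-9 of the totals
#' @return object of class `population_matrix`: list with `delays`, the
#'   full `states` matrix (delays x 11 sub-populations), and `species`
#'   (delays x 3 observable populations `I1`, `I2`, `I3` where
#'   `I1 = I1_full + I1_part + I1_lig` etc.)
#' @export
solve_populations <- function(params, delays, rtol = 1e-11, atol = 1e-14) {
  stopifnot(inherits(params, "kinetic_params"), all(delays > 0))
  y0 <- setNames(numeric(11), .state_names)
  y0["I1_full"] <- params$phi_full * params$P0
  y0["I1_part"] <- (1 - params$phi_full) * params$P0
  y0["CO"] <- params$CO_excess
  p <- c(params$tau12, params$tau_gem, params$tau_rt1, params$tau_rt2,
         params$tau_lig, params$k_bi, params$f_gem, params$phi_full)
  times <- c(0, delays)
  sol <- deSolve::lsoda(y0, times, func = "hbi_derivs", parms = p,
                        dllname = "trxss", initfunc = "hbi_initparms",
                        rtol = rtol, atol = atol, maxsteps = 50000)
  if (attr(sol, "istate")[1] < 0) stop("ODE integration failed")
  states <- sol[-1, -1, drop = FALSE]
  colnames(states) <- .state_names
  if (any(states < -1e-6 * params$P0)) {
    stop("negative concentrations beyond solver tolerance; ",
         "integration or scheme error")
  }
  states[states < 0] <- 0
  species <- cbind(
    I1 = states[, "I1_full"] + states[, "I1_part"] + states[, "I1_lig"],
    I2 = states[, "I2_full_gem"] + states[, "I2_full_rt"] +
      states[, "I2_part_gem"] + states[, "I2_part_rt"],
    I3 = states[, "I3_full"] + states[, "I3_part"])
  out <- list(delays = delays, states = states, species = species,
              params = params)
  class(out) <- "population_matrix"
  out
}

#' Model difference-curve matrix from populations and species curves
#'
#' ΔS_model(q, t) = sum over species X of population_X(t) * ΔS_X(q). The
#' recovered ground state contributes zero by construction because all
#' curves are differences against the ground state.
#'
#' @param params a [kinetic_params()]
#' @param species_curves list of three `trxss_curve`s named `I1`, `I2`,
#'   `I3` on a common q grid
#' @param delays time delays (s)
#' @param populations optional precomputed [solve_populations()] result
#' @return a `trxss_diffmat`
#' @export
model_matrix <- function(params, species_curves, delays,
                         populations = NULL) {
  q <- species_curves[[1]]$q
  for (cu in species_curves) {
    if (length(cu$q) != length(q) || any(abs(cu$q - q) > 1e-12)) {
      stop("species curves must share one q grid")
    }
  }
  if (is.null(populations)) populations <- solve_populations(params, delays)
  S <- vapply(c("I1", "I2", "I3"),
              function(nm) species_curves[[nm]]$intensity,
              numeric(length(q)))
  vals <- S %*% t(populations$species)
  difference_matrix(q, delays, vals)
}

#' Cooperativity ratio of the R-T transition
#'
#' Ratio of the slower to the faster R-T time constant,
#' tau_RT2 / tau_RT1 (>= 1 by the sorting invariant of
#' [kinetic_params()]). A smaller ratio means the partially photolyzed
#' substate switches almost as fast as the fully photolyzed one, i.e.
#' stronger intersubunit coupling.
#'
#' @param params a [kinetic_params()]
#' @return numeric ratio
#' @export
cooperativity_ratio <- function(params) {
  stopifnot(inherits(params, "kinetic_params"))
  params$tau_rt2 / params$tau_rt1
}

# ---- global kinetic fit -------------------------------------------------

# parameter transform: theta (unconstrained) <-> kinetic_params.
# time constants and k_bi in log space; tau_rt2 = tau_rt1 * (1 + exp(u))
# keeps the ordering; fractions in logit space.
theta_from_params <- function(p) {
  c(log(p$tau12), log(p$tau_gem), log(p$tau_rt1),
    log(max(p$tau_rt2 / p$tau_rt1 - 1, 1e-6)),
    log(p$tau_lig), log(p$k_bi),
    stats::qlogis(min(max(p$f_gem, 1e-6), 1 - 1e-6)),
    stats::qlogis(min(max(p$phi_full, 1e-6), 1 - 1e-6)))
}

params_from_theta <- function(theta, P0, CO_excess) {
  rt1 <- exp(theta[3])
  kinetic_params(tau12 = exp(theta[1]), tau_gem = exp(theta[2]),
                 tau_rt1 = rt1, tau_rt2 = rt1 * (1 + exp(theta[4])),
                 tau_lig = exp(theta[5]), k_bi = exp(theta[6]),
                 f_gem = stats::plogis(theta[7]),
                 phi_full = stats::plogis(theta[8]),
                 P0 = P0, CO_excess = CO_excess)
}

#' Globally fit the kinetic model to a difference-curve matrix
#'
#' Nested optimisation following the standard TRXSS analysis: the data
#' matrix is projected onto the subspace of the significant left singular
#' vectors; for each trial set of nonlinear kinetic parameters the
#' populations are solved, the species-associated difference curves are
#' obtained by linear least squares of the projected data against the
#' population matrix, and the residual is minimised over the nonlinear
#' parameters with a multi-start Nelder-Mead search.
#'
#' `P0` and `CO_excess` are taken from `init` and held fixed (they set the
#' concentration scale, which is degenerate with the curve amplitudes).
#'
#' @param data a `trxss_diffmat`
#' @param init initial [kinetic_params()] guess (order-of-magnitude
#'   starting values suffice)
#' @param svd a [svd_decompose()] result with at least 3 significant
#'   components (run [count_significant()] first)
#' @param n_starts number of multi-start replicates; starts beyond the
#'   first perturb the initial time constants by +/-0.3 in log10 and the
#'   fractions by +/-0.5 in logit units
#' @param n_polish how many of the best stage-one starts are polished to
#'   tight tolerance
#' @param seed RNG seed for the start perturbations
#' @param rtol ODE tolerance used inside the objective
#' @return list with `params` (fitted [kinetic_params()]),
#'   `species_curves` (list of three `trxss_curve`s), `populations`,
#'   `chisq_red` (reduced chi-square against the full data), `residual`
#'   (subspace residual norm), `converged`, and `starts` (per-start
#'   residuals)
#' @export
fit_kinetic_model <- function(data, init = kinetic_params(
                                tau12 = 5e-9, tau_gem = 2e-7,
                                tau_rt1 = 3e-7, tau_rt2 = 3e-6,
                                tau_lig = 2e-5, k_bi = 100,
                                f_gem = 0.3, phi_full = 0.7),
                              svd, n_starts = 16, n_polish = 3,
                              seed = 1, rtol = 1e-8) {
  k <- svd$n_significant
  if (is.null(k) || is.na(k) || k < 3) {
    stop("svd must have at least 3 significant components; ",
         "run count_significant() first")
  }
  U <- svd$u[, seq_len(k), drop = FALSE]
  M <- t(U) %*% data$values            # k x n_delays reduced data
  delays <- data$delays
  P0 <- init$P0
  CO_excess <- init$CO_excess

  objective <- function(theta) {
    p <- tryCatch(params_from_theta(theta, P0, CO_excess),
                  error = function(e) NULL)
    if (is.null(p)) return(1e30)
    pop <- tryCatch(solve_populations(p, delays, rtol = rtol,
                                      atol = rtol * 1e-3),
                    error = function(e) NULL)
    if (is.null(pop)) return(1e30)
    C <- pop$species                   # n_delays x 3
    G <- crossprod(C)
    if (rcond(G) < 1e-12) return(1e30)
    A <- M %*% C %*% solve(G)          # k x 3 amplitudes
    sum((M - A %*% t(C))^2)
  }

  theta0 <- theta_from_params(init)
  set.seed(seed)
  # the fully/partially photolyzed substates are nearly exchangeable
  # (phi_full <-> 1 - phi_full with swapped R-T constants), so half the
  # starts begin from the mirrored fraction to cover both basins
  starts <- lapply(seq_len(n_starts), function(i) {
    th <- theta0
    if (i > 2L) {
      th[1:6] <- th[1:6] + runif(6, -0.3, 0.3) * log(10)
      th[7:8] <- th[7:8] + runif(2, -0.5, 0.5)
    }
    if (i %% 2 == 0L) th[8] <- -th[8]
    th
  })
  stage1 <- lapply(starts, function(th) {
    optim(th, objective, method = "Nelder-Mead",
          control = list(maxit = 400, reltol = 1e-10))
  })
  ord <- order(vapply(stage1, `[[`, numeric(1), "value"))
  best <- NULL
  for (i in head(ord, n_polish)) {
    fit <- stage1[[i]]
    # restarted Nelder-Mead: a fresh simplex escapes the premature
    # collapse the method is prone to in 8 dimensions
    for (round in 1:6) {
      prev <- fit$value
      fit <- optim(fit$par, objective, method = "Nelder-Mead",
                   control = list(maxit = 4000, reltol = 1e-14))
      if (prev - fit$value <= 1e-10 * max(prev, 1e-300)) break
    }
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  converged <- is.finite(best$value) && best$value < 1e29
  params <- params_from_theta(best$par, P0, CO_excess)
  pop <- solve_populations(params, delays)
  C <- pop$species
  G <- crossprod(C)
  if (rcond(G) < 1e-12) {
    corm <- stats::cor(C)
    diag(corm) <- 0
    pair <- which(abs(corm) == max(abs(corm)), arr.ind = TRUE)[1, ]
    stop("rank-deficient population matrix: species ",
         colnames(C)[pair[1]], " and ", colnames(C)[pair[2]],
         " have proportional populations")
  }
  A <- M %*% C %*% solve(G)
  Sq <- U %*% A                        # q x 3 species curves
  curves <- setNames(lapply(1:3, function(j)
    scattering_curve(data$q, Sq[, j])), c("I1", "I2", "I3"))
  resid_full <- data$values - Sq %*% t(C)
  sig <- if (!is.null(data$sigma)) data$sigma else 1
  npar <- 8 + length(A)
  chisq_red <- sum((resid_full / sig)^2) /
    max(length(resid_full) - npar, 1)
  list(params = params, species_curves = curves, populations = pop,
       chisq_red = chisq_red, residual = best$value, converged = converged,
       starts = vapply(stage1, `[[`, numeric(1), "value"))
}
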