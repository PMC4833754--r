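#' Partition a structure into rigid bodies
#'
#' Helices and hemes are the basic rigid units (18 bodies for a two-chain
#' HbI-like dimer: 8 helices + 1 heme per subunit). The segment table maps
#' residue ranges to helix names per chain; residues falling between
#' segments (loops) are assigned to the nearest preceding helix, and an
#' N-terminal tail to the chain's first helix. Heme groups become their
#' own bodies, and attached waters stay in (or are assigned to) their
#' host heme body so they move rigidly with it.
#'
#' @param structure a `trxss_structure`
#' @param segments data frame with columns `chain`, `start`, `end`,
#'   `body`
#' @return object of class `rigid_body_model`: list with `bodies` (named
#'   list of atom index vectors, a partition of all atoms), `connectivity`
#'   (data frame `i`, `j`, `d0` of backbone link atoms between
#'   sequence-adjacent bodies and their template gap distances), and
#'   `n_bodies`
#' @export
define_rigid_bodies <- function(structure, segments) {
  stopifnot(all(c("chain", "start", "end", "body") %in% names(segments)))
  body <- rep(NA_character_, nrow(structure))
  for (ch in unique(segments$chain)) {
    seg <- segments[segments$chain == ch, ]
    seg <- seg[order(seg$start), ]
    # overlapping ranges would assign a residue twice
    if (nrow(seg) > 1 && any(seg$start[-1] <= seg$end[-nrow(seg)])) {
      stop("segment table covers a residue twice in chain ", ch)
    }
    prot <- which(structure$chain == ch & structure$resid != "HEM" &
                    !structure$is_water)
    for (i in prot) {
      r <- structure$resno[i]
      hit <- which(seg$start <= r & r <= seg$end)
      if (length(hit) == 0L) {
        prev <- which(seg$end < r)
        hit <- if (length(prev) > 0L) max(prev) else 1L
      }
      body[i] <- paste(ch, seg$body[hit], sep = ":")
    }
  }
  prot_all <- which(structure$resid != "HEM" & !structure$is_water)
  if (any(is.na(body[prot_all]))) {
    ch <- unique(structure$chain[prot_all[is.na(body[prot_all])]])
    stop("protein atoms in chain(s) ", paste(ch, collapse = ", "),
         " not covered by the segment table")
  }
  heme <- which(structure$resid == "HEM")
  body[heme] <- paste(structure$chain[heme], "heme", sep = ":")
  heme_bodies <- unique(body[heme])
  wat <- which(structure$is_water)
  for (i in wat) {
    if (!is.na(structure$body[i]) && structure$body[i] %in% heme_bodies) {
      body[i] <- structure$body[i]
    } else {
      if (length(heme_bodies) == 0L) stop("waters present but no heme body")
      cent <- vapply(heme_bodies, function(hb) {
        sqrt(sum((coords(structure, i)[1, ] -
                    atom_centroid(structure, which(body == hb)))^2))
      }, numeric(1))
      body[i] <- heme_bodies[which.min(cent)]
    }
  }
  # body order: per chain, helices in segment order, then the heme
  ord <- unlist(lapply(unique(segments$chain), function(ch) {
    seg <- segments[segments$chain == ch, ]
    seg <- seg[order(seg$start), ]
    c(paste(ch, seg$body, sep = ":"),
      if (paste(ch, "heme", sep = ":") %in% body) paste(ch, "heme", sep = ":"))
  }))
  ord <- ord[ord %in% body]
  bodies <- lapply(ord, function(b) which(body == b))
  names(bodies) <- ord
  # backbone connectivity between sequence-adjacent helices
  conn <- do.call(rbind, lapply(unique(segments$chain), function(ch) {
    seg <- segments[segments$chain == ch, ]
    seg <- seg[order(seg$start), ]
    if (nrow(seg) < 2L) return(NULL)
    do.call(rbind, lapply(seq_len(nrow(seg) - 1L), function(k) {
      bi <- bodies[[paste(ch, seg$body[k], sep = ":")]]
      bj <- bodies[[paste(ch, seg$body[k + 1L], sep = ":")]]
      ca_i <- bi[structure$elety[bi] == "CA"]
      ca_j <- bj[structure$elety[bj] == "CA"]
      if (length(ca_i) == 0L || length(ca_j) == 0L) return(NULL)
      i <- ca_i[which.max(structure$resno[ca_i])]
      j <- ca_j[which.min(structure$resno[ca_j])]
      data.frame(i = i, j = j,
                 d0 = sqrt(sum((coords(structure, i)[1, ] -
                                  coords(structure, j)[1, ])^2)))
    }))
  }))
  out <- list(bodies = bodies, connectivity = conn, n_bodies = length(bodies),
              assignment = body)
  class(out) <- "rigid_body_model"
  out
}

#' @export
print.rigid_body_model <- function(x, ...) {
  cat(sprintf("<rigid_body_model> %d bodies, %d connectivity links\n",
              x$n_bodies, if (is.null(x$connectivity)) 0 else nrow(x$connectivity)))
  invisible(x)
}

#' Scale-fitted chi-square between a model and a target curve
#'
#' chi^2 = 1/(N-1) sum_i ((c m_i - t_i) / sigma_i)^2 with the
#' multiplicative scale c solved analytically by weighted least squares,
#' c = sum(m t / sigma^2) / sum(m^2 / sigma^2), restricted to c > 0: a
#' non-positive optimum (anticorrelated model) is clipped to a small
#' positive floor, 1% of the natural target/model magnitude ratio, so
#' that anticorrelation is penalised rather than plateauing - without
#' this, Monte Carlo moves see a flat landscape wherever the model is
#' anticorrelated with the target. The free scale reflects the arbitrary
#' units of difference scattering data.
#'
#' @param model,target numeric vectors or `trxss_curve`s on one grid
#' @param sigma per-point uncertainties (default: `target$sigma` if
#'   present, else 1)
#' @return list with `chisq` and fitted `scale`
#' @export
chi_square <- function(model, target, sigma = NULL) {
  if (inherits(target, "trxss_curve")) {
    if (is.null(sigma) && !is.null(target$sigma)) sigma <- target$sigma
    target <- target$intensity
  }
  if (inherits(model, "trxss_curve")) model <- model$intensity
  if (length(model) != length(target)) stop("length mismatch")
  if (is.null(sigma)) sigma <- 1
  if (all(model == 0)) stop("all-zero model curve")
  w <- 1 / sigma^2
  cc <- sum(w * model * target) / sum(w * model^2)
  cc <- max(cc, 0.01 * sqrt(sum(w * target^2) / sum(w * model^2)))
  chisq <- sum(w * (cc * model - target)^2) / (length(model) - 1)
  list(chisq = chisq, scale = cc)
}

#' Default Monte Carlo schedule
#'
#' The run has two phases. During the exploration phase (the first
#' `explore_frac` of the steps) moves are proposed at full amplitude and
#' accepted by the Metropolis rule with an effective temperature annealed
#' geometrically from T0 to `T_end_factor * T0`; T0 is calibrated to
#' `T0_mult` times the median |change in objective| over `n_probe` random
#' probe moves, which makes the schedule independent of the (arbitrary)
#' absolute chi-square units. The remaining steps are a zero-temperature
#' polish in which only improvements are accepted and the move amplitude
#' shrinks geometrically to `amp_end` of its initial value.
#'
#' @param n_steps number of MC steps
#' @param sigma_rot rotation move amplitude (degrees, sd of the normal
#'   angle draw)
#' @param sigma_trans translation move amplitude (Angstrom per axis)
#' @param explore_frac fraction of steps in the annealed exploration phase
#' @param T0_mult starting temperature as a multiple of the median probe
#'   move size
#' @param T_end_factor final temperature as a fraction of the start
#' @param amp_end final move-amplitude factor of the polish phase
#' @param n_probe number of probe moves used to calibrate T0
#' @param w_conn weight of the backbone-connectivity penalty (per
#'   Angstrom^2)
#' @param p_group probability that a move displaces all bodies of one
#'   chain rigidly instead of a single body (default 0: single-body
#'   moves keep the search local to the template, which is the implicit
#'   regulariser of template-based rigid-body refinement - wide
#'   collective excursions can trade the quaternary angle against
#'   compensating tertiary motions at nearly unchanged chi-square)
#' @param w_clash weight of the soft-sphere excluded-volume penalty (per
#'   Angstrom^2); without it rigid bodies interpenetrate freely and can
#'   overfit the curve with unphysical packings
#' @param clash_rmin soft-sphere contact distance (Angstrom)
#' @param clash_slack contacts natively closer than `clash_rmin` are
#'   allowed down to this fraction of their template separation
#' @return named list
#' @export
mc_schedule <- function(n_steps = 3000, sigma_rot = 2, sigma_trans = 0.3,
                        explore_frac = 0.3, T0_mult = 0.5, T_end_factor = 1e-3,
                        amp_end = 0.02, n_probe = 20, w_conn = 10,
                        p_group = 0, w_clash = 0, clash_rmin = 3,
                        clash_slack = 0.9) {
  list(n_steps = n_steps, sigma_rot = sigma_rot, sigma_trans = sigma_trans,
       explore_frac = explore_frac, T0_mult = T0_mult,
       T_end_factor = T_end_factor, amp_end = amp_end, n_probe = n_probe,
       w_conn = w_conn, p_group = p_group, w_clash = w_clash,
       clash_rmin = clash_rmin, clash_slack = clash_slack)
}

# internal: cached fast Debye evaluation context for repeated calls on one
# atom composition
.debye_context <- function(structure, q, mode, rho_s, bin) {
  sp <- atom_species(structure, q, mode, rho_s)
  list(species = sp$species, fq = sp$fq, q = q, bin = bin)
}

.debye_eval <- function(xyz, ctx) {
  .debye_hist_cpp(xyz, ctx$species, ctx$fq, ctx$q, ctx$bin)
}

conn_penalty <- function(xyz, conn) {
  if (is.null(conn) || nrow(conn) == 0L) return(0)
  d <- sqrt(rowSums((xyz[conn$i, , drop = FALSE] -
                       xyz[conn$j, , drop = FALSE])^2))
  sum((d - conn$d0)^2)
}

#' Rigid-body Monte Carlo refinement against a difference curve
#'
#' Minimises chi^2 between the model difference curve
#' I(candidate) - I(reference) and the target species-associated
#' difference curve, plus a backbone-connectivity penalty
#' `w_conn * sum (d - d0)^2` over the gaps between sequence-adjacent
#' bodies (without it free rigid bodies would tear the chain). At each
#' step one randomly chosen body receives a random rotation (axis uniform
#' on the sphere, angle ~ N(0, sigma_rot)) and translation
#' (~ N(0, sigma_trans) per axis); moves are accepted by the Metropolis
#' rule with a geometrically annealed effective temperature. The
#' best-so-far structure is returned.
#'
#' @param template starting `trxss_structure`
#' @param contact_ref structure defining the native inter-body contacts
#'   for the clash penalty (default: `template`); [run_ensemble()] passes
#'   the unperturbed template
#' @param bodies a [define_rigid_bodies()] model for `template`
#' @param target target difference curve (`trxss_curve`); its q grid
#'   defines the fit window
#' @param reference ligated-state reference structure used to form model
#'   difference curves
#' @param schedule a [mc_schedule()] list
#' @param seed RNG seed
#' @param mode,bin,rho_s Debye options (histogram path is used throughout)
#' @return list with `structure` (best candidate), `chisq` (its
#'   scale-fitted chi-square), `objective` (chisq + penalty), `trace`
#'   (summary: acceptance rate, objective by step thinned), `scale`
#' @export
mc_refine <- function(template, bodies, target, reference,
                      schedule = mc_schedule(), seed = 1,
                      mode = "vacuum", bin = 0.1, rho_s = 0.334,
                      contact_ref = template) {
  if (schedule$n_steps < 1) stop("schedule must have at least one step")
  q <- target$q
  # for targets without uncertainties, normalising by the target RMS makes
  # chi^2 dimensionless and O(1) (0 = perfect fit, ~1 = no fit), which
  # puts the connectivity penalty (w_conn per A^2) on a meaningful scale
  sigma <- if (!is.null(target$sigma)) target$sigma
           else sqrt(mean(target$intensity^2))
  ctx <- .debye_context(template, q, mode, rho_s, bin)
  I_ref <- .debye_eval(coords(reference), ctx = .debye_context(
    reference, q, mode, rho_s, bin))
  tgt <- target$intensity

  set.seed(seed)
  xyz <- coords(template)
  ref_xyz <- coords(contact_ref)
  body_id <- match(bodies$assignment, names(bodies$bodies)) - 1L
  w_clash <- if (is.null(schedule$w_clash)) 0 else schedule$w_clash
  eval_obj <- function(xyz) {
    ds <- .debye_eval(xyz, ctx) - I_ref
    cs <- chi_square(ds, tgt, sigma)
    pen <- schedule$w_conn * conn_penalty(xyz, bodies$connectivity)
    if (w_clash > 0) {
      pen <- pen + w_clash *
        .clash_penalty_cpp(xyz, ref_xyz, body_id, schedule$clash_rmin,
                           schedule$clash_slack)
    }
    list(obj = cs$chisq + pen, chisq = cs$chisq, scale = cs$scale)
  }
  cur <- eval_obj(xyz)
  best <- list(xyz = xyz, obj = cur$obj, chisq = cur$chisq,
               scale = cur$scale)
  nb <- length(bodies$bodies)
  chain_groups <- split(seq_len(nb),
                        sub(":.*$", "", names(bodies$bodies)))
  pg <- if (is.null(schedule$p_group)) 0 else schedule$p_group
  propose <- function(xyz, amp) {
    bi <- if (length(chain_groups) > 1 && runif(1) < pg) {
      unlist(bodies$bodies[chain_groups[[sample.int(length(chain_groups),
                                                    1)]]], use.names = FALSE)
    } else {
      bodies$bodies[[sample.int(nb, 1)]]
    }
    sub <- xyz[bi, , drop = FALSE]
    cen <- colMeans(sub)
    R <- rotation_matrix(rnorm(3), rnorm(1, 0, amp * schedule$sigma_rot))
    tr <- rnorm(3, 0, amp * schedule$sigma_trans)
    xyz[bi, ] <- sweep(sweep(sub, 2, cen) %*% t(R), 2, cen + tr, FUN = "+")
    xyz
  }
  # calibrate T0 from the typical |delta objective| of probe moves so the
  # exploration phase behaves the same regardless of the (arbitrary)
  # absolute chi^2 units
  probe <- replicate(schedule$n_probe,
                     abs(eval_obj(propose(xyz, 1))$obj - cur$obj))
  T0 <- schedule$T0_mult * max(median(probe), 1e-12)
  n_explore <- round(schedule$explore_frac * schedule$n_steps)
  n_polish <- schedule$n_steps - n_explore
  t_decay <- schedule$T_end_factor^(1 / max(n_explore - 1, 1))
  a_decay <- schedule$amp_end^(1 / max(n_polish - 1, 1))
  n_acc <- 0L
  thin <- max(1L, schedule$n_steps %/% 200L)
  trace_steps <- integer(0)
  trace_obj <- numeric(0)
  Tk <- T0
  amp <- 1
  for (step in seq_len(schedule$n_steps)) {
    exploring <- step <= n_explore
    newxyz <- propose(xyz, amp)
    prop <- eval_obj(newxyz)
    accept <- prop$obj <= cur$obj ||
      (exploring && Tk > 0 && runif(1) < exp(-(prop$obj - cur$obj) / Tk))
    if (accept) {
      xyz <- newxyz
      cur <- prop
      n_acc <- n_acc + 1L
      if (cur$obj < best$obj) {
        best <- list(xyz = xyz, obj = cur$obj, chisq = cur$chisq,
                     scale = cur$scale)
      }
    }
    if (step %% thin == 0L) {
      trace_steps <- c(trace_steps, step)
      trace_obj <- c(trace_obj, cur$obj)
    }
    if (exploring) Tk <- Tk * t_decay else amp <- amp * a_decay
    if (step == n_explore) {
      # polish phase starts from the best structure found so far
      xyz <- best$xyz
      cur <- best
    }
  }
  out_struct <- set_coords(template, best$xyz)
  list(structure = out_struct, chisq = best$chisq, objective = best$obj,
       scale = best$scale,
       trace = list(acceptance_rate = n_acc / schedule$n_steps,
                    step = trace_steps, objective = trace_obj))
}

#' Multi-start rigid-body refinement ensemble
#'
#' Runs [mc_refine()] from `n_starts` randomly perturbed copies of the
#' template (every body moved with the same move distributions at the
#' given perturbation amplitudes), each with a seed derived from the
#' master seed, and selects the candidate ensemble by a chi-square
#' threshold rule: relative (`chisq <= threshold * min chisq`, the
#' default) or absolute (`chisq <= threshold`). The default relative
#' factor of 3 is wider than the chi-square spread of a converged run;
#' a tight factor would collapse the ensemble onto the single luckiest
#' start and ensemble statistics would lose meaning.
#'
#' @param template,bodies,target,reference,schedule,mode,bin,rho_s as in
#'   [mc_refine()]
#' @param n_starts number of independent starts (>= 1)
#' @param perturb_rot,perturb_trans start-perturbation amplitudes
#'   (degrees / Angstrom)
#' @param threshold threshold value (default 3, relative)
#' @param max_retries how many times a start whose refinement never
#'   leaves the no-fit plateau is redrawn with a fresh derived seed
#' @param threshold_type `"relative"` or `"absolute"`
#' @param seed master seed; a fixed master seed gives a bit-identical
#'   candidate list on rerun
#' @return object of class `refinement_result`: list with `candidates`
#'   (all refined structures sorted by chi-square), `chisq`, `seeds`,
#'   `start_index`, `selected` (logical), `ensemble` (selected
#'   structures), `threshold_used`, `acceptance` (per-start rates),
#'   `empty` flag (TRUE with a warning when nothing passes an absolute
#'   threshold)
#' @export
run_ensemble <- function(template, bodies, target, reference,
                         n_starts = 20, perturb_rot = 2, perturb_trans = 0.3,
                         threshold = 3,
                         threshold_type = c("relative", "absolute"),
                         schedule = mc_schedule(), seed = 1,
                         max_retries = 2,
                         mode = "vacuum", bin = 0.1, rho_s = 0.334) {
  threshold_type <- match.arg(threshold_type)
  stopifnot(n_starts >= 1)
  set.seed(seed)
  start_seeds <- sample.int(.Machine$integer.max - 10L, n_starts)
  # a run that never leaves the no-fit plateau (chi-square still at the
  # order of the null model's) is an optimisation failure, not a
  # candidate; such starts are redrawn a couple of times with a fresh
  # derived seed so they do not silently shrink the ensemble
  sig <- if (!is.null(target$sigma)) target$sigma
         else sqrt(mean(target$intensity^2))
  chi_null <- sum((target$intensity / sig)^2) / (length(target$q) - 1)
  runs <- lapply(seq_len(n_starts), function(i) {
    r <- NULL
    for (attempt in 0:max_retries) {
      s <- start_seeds[i] + 3L * attempt
      set.seed(s)
      start <- perturb_bodies(template, bodies, perturb_rot, perturb_trans)
      r <- mc_refine(start, bodies, target, reference, schedule = schedule,
                     seed = s + 1L, mode = mode, bin = bin,
                     rho_s = rho_s, contact_ref = template)
      if (r$chisq < 0.5 * chi_null) break
    }
    r
  })
  chisq <- vapply(runs, `[[`, numeric(1), "chisq")
  ord <- order(chisq)
  chisq <- chisq[ord]
  cand <- lapply(runs[ord], `[[`, "structure")
  cutoff <- if (threshold_type == "relative") threshold * min(chisq)
            else threshold
  selected <- chisq <= cutoff
  empty <- !any(selected)
  if (empty) warning("no candidate passes the chi-square threshold")
  out <- list(candidates = cand, chisq = chisq,
              seeds = start_seeds[ord], start_index = ord,
              selected = selected, ensemble = cand[selected],
              threshold_used = cutoff,
              acceptance = vapply(runs[ord], function(r)
                r$trace$acceptance_rate, numeric(1)),
              empty = empty)
  class(out) <- "refinement_result"
  out
}

#' @export
print.refinement_result <- function(x, ...) {
  cat(sprintf("<refinement_result> %d candidates, %d selected (chi2 <= %.4g)\n",
              length(x$candidates), sum(x$selected), x$threshold_used))
  cat(sprintf("  best chi2 %.4g, worst %.4g\n", min(x$chisq), max(x$chisq)))
  invisible(x)
}
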