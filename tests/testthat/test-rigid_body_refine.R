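test_that("the HbI-like dimer partitions into 18 rigid bodies with waters on their hemes", {
  st <- toy_dimer()
  model <- toy_bodies()
  expect_equal(model$n_bodies, 18L)
  # partition: every atom in exactly one body
  all_idx <- sort(unname(unlist(model$bodies)))
  expect_equal(all_idx, seq_len(nrow(st)))
  # waters land in their host heme body
  wat <- which(st$is_water)
  expect_true(all(model$assignment[wat] %in% c("A:heme", "B:heme")))
  expect_true(all(model$assignment[wat] == st$body[wat]))
  # 7 inter-helix links per chain
  expect_equal(nrow(model$connectivity), 14L)
})

test_that("loop residues attach to the preceding helix and overlaps are rejected", {
  st <- toy_dimer()
  segs <- attr(st, "segments")
  # open a gap: residues 53-60 now precede helE, which starts at 61
  segs$start[segs$body == "helE"] <- 61
  model <- define_rigid_bodies(st, segs)
  gap_atoms <- which(st$chain == "A" & st$resno %in% 53:60 &
                       st$resid != "HEM" & !st$is_water)
  expect_true(all(model$assignment[gap_atoms] == "A:helD"))
  # N-terminal tail goes to the first helix
  segs2 <- attr(st, "segments")
  segs2$start[segs2$body == "helA"] <- 5
  model2 <- define_rigid_bodies(st, segs2)
  expect_true(all(model2$assignment[st$chain == "B" & st$resno < 5 &
                                      st$resid != "HEM" & !st$is_water]
                  == "B:helA"))
  # overlapping ranges cover a residue twice
  segs3 <- attr(st, "segments")
  segs3$end[segs3$body == "helA"] <- 30
  expect_error(define_rigid_bodies(st, segs3), "twice")
  # a chain missing from the table is an error
  segs4 <- attr(st, "segments")
  expect_error(define_rigid_bodies(st, segs4[segs4$chain == "A", ]),
               "not covered")
})

test_that("chi_square honours scale freedom and matches a brute-force scan of c", {
  m <- c(1, 2, 3, 4, 2)
  expect_equal(chi_square(m, m)$chisq, 0)
  expect_equal(chi_square(m, 3.7 * m)$chisq, 0, tolerance = 1e-12)
  t <- c(1.2, 1.7, 3.4, 3.6, 2.2)
  s <- c(0.5, 1, 0.7, 2, 1)
  got <- chi_square(m, t, s)
  grid <- seq(0.1, 3, by = 1e-5)
  scan <- vapply(grid, function(cc) sum(((cc * m - t) / s)^2) / 4,
                 numeric(1))
  expect_equal(got$chisq, min(scan), tolerance = 1e-6)
  expect_equal(got$scale, grid[which.min(scan)], tolerance = 1e-3)
  # an anticorrelated model gets a small positive floor scale and a
  # chi-square above the no-fit level, so the misfit stays informative
  neg <- chi_square(m, -t, s)
  expect_gt(neg$scale, 0)
  expect_lt(neg$scale, 0.05)
  no_fit <- sum((t / s)^2) / (length(t) - 1)
  expect_gte(neg$chisq, no_fit)
  expect_error(chi_square(rep(0, 5), t), "all-zero")
})

test_that("the refinement objective reduces to chi_square when connectivity is off", {
  st <- toy_dimer()
  model <- toy_bodies()
  q <- seq(0.15, 1, length.out = 50)
  inter <- make_intermediates(st, seed = 2)
  target <- difference_curve(inter$I3, st, q)
  set.seed(31)
  start <- trxss:::perturb_bodies(st, model, 2, 0.3)
  r0 <- mc_refine(start, model, target, st,
                  schedule = mc_schedule(n_steps = 5, w_conn = 0), seed = 1)
  expect_equal(r0$objective, r0$chisq, tolerance = 1e-12)
  rw <- mc_refine(start, model, target, st,
                  schedule = mc_schedule(n_steps = 5, w_conn = 10), seed = 1)
  pen <- trxss:::conn_penalty(coords(rw$structure), model$connectivity)
  expect_equal(rw$objective, rw$chisq + 10 * pen, tolerance = 1e-10)
})

test_that("rigid moves preserve intra-body distances to 1e-9 A", {
  st <- toy_dimer()
  model <- toy_bodies()
  set.seed(5)
  moved <- trxss:::perturb_bodies(st, model, sigma_rot = 4, sigma_trans = 1)
  for (b in model$bodies[c(1, 9, 17, 18)]) {
    expect_equal(as.vector(dist(coords(moved, b))),
                 as.vector(dist(coords(st, b))), tolerance = 1e-9)
  }
})

test_that("zero-temperature refinement is greedy and self-targets stay converged", {
  st <- toy_dimer()
  model <- toy_bodies()
  q <- seq(0.15, 1, length.out = 80)
  inter <- make_intermediates(st, seed = 3)
  # self-target: the target is the template's own difference curve, and
  # the body model (hence the connectivity reference gaps) is built from
  # that same template
  model3 <- define_rigid_bodies(inter$I3, attr(st, "segments"))
  self_target <- difference_curve(inter$I3, st, q)
  sched <- mc_schedule(n_steps = 400, T0_mult = 0, explore_frac = 0.5)
  r <- mc_refine(inter$I3, model3, self_target, st, schedule = sched,
                 seed = 9)
  expect_lte(r$chisq, 1e-3)
  # greedy: accepted objective sequence never increases
  expect_true(all(diff(r$trace$objective) <= 1e-12))
})

test_that("refinement against a known target reduces the misfit and recovers the quaternary angle", {
  st <- toy_dimer()
  model <- toy_bodies()
  q <- seq(0.15, 1, length.out = 100)
  inter <- make_intermediates(st, rotation = 3.7, seed = 1)
  target <- difference_curve(inter$I3, st, q)
  sigma <- sqrt(mean(target$intensity^2))
  sched <- mc_schedule()
  chi0 <- chi1 <- aerr0 <- aerr1 <- rmsd1 <- numeric(3)
  for (i in 1:3) {
    set.seed(100 + i)
    start <- trxss:::perturb_bodies(st, model, 2, 0.3)
    r <- mc_refine(start, model, target, st, schedule = sched,
                   seed = 200 + i)
    ds0 <- difference_curve(debye_intensity(start, q, method = "histogram"),
                            debye_intensity(st, q, method = "histogram"))
    chi0[i] <- chi_square(ds0$intensity, target$intensity, sigma)$chisq
    chi1[i] <- r$chisq
    aerr0[i] <- abs(subunit_rotation_angle(start, st) - 3.7)
    aerr1[i] <- abs(subunit_rotation_angle(r$structure, st) - 3.7)
    rmsd1[i] <- ca_rmsd(r$structure, inter$I3)
  }
  # the misfit collapses and the quaternary angle moves onto the truth;
  # the Calpha RMSD stays bounded by the width of the curve-compatible
  # manifold (it is not itself the refined quantity)
  expect_true(all(chi1 < chi0))
  expect_lt(median(chi1), 0.3)
  expect_lt(median(aerr1), median(aerr0))
  expect_lt(max(rmsd1), 3)
})

test_that("ensembles are deterministic, sorted, and monotone under the threshold", {
  st <- toy_dimer()
  model <- toy_bodies()
  q <- seq(0.15, 1, length.out = 60)
  inter <- make_intermediates(st, seed = 4)
  target <- difference_curve(inter$I3, st, q)
  sched <- mc_schedule(n_steps = 150)
  e1 <- run_ensemble(st, model, target, st, n_starts = 3, schedule = sched,
                     seed = 11)
  e2 <- run_ensemble(st, model, target, st, n_starts = 3, schedule = sched,
                     seed = 11)
  expect_identical(lapply(e1$candidates, coords),
                   lapply(e2$candidates, coords))
  expect_identical(e1$chisq, e2$chisq)
  expect_true(!is.unsorted(e1$chisq))
  # raising the threshold never removes a candidate
  loose <- run_ensemble(st, model, target, st, n_starts = 3,
                        schedule = sched, seed = 11, threshold = 6)
  expect_true(all(which(e1$selected) %in% which(loose$selected)))
  single <- run_ensemble(st, model, target, st, n_starts = 1,
                         schedule = sched, seed = 3)
  expect_lte(length(single$ensemble), 1L)
  expect_warning(
    none <- run_ensemble(st, model, target, st, n_starts = 2,
                         schedule = sched, seed = 5, threshold = 1e-12,
                         threshold_type = "absolute"),
    "threshold")
  expect_true(none$empty)
  expect_length(none$ensemble, 0L)
})
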