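test_that("E-F distance is the per-subunit Calpha separation and is rigid-motion invariant", {
  mk <- function(d_a, d_b) {
    structure_from_atoms(data.frame(
      element = "C", elety = "CA", resid = "ALA",
      resno = rep(c(66, 102), 2), chain = rep(c("A", "B"), each = 2),
      x = c(0, d_a, 5, 5 + d_b), y = c(0, 0, 8, 8), z = 0,
      stringsAsFactors = FALSE))
  }
  st <- mk(20, 20)
  expect_equal(ef_distance(st)$mean, 20)
  asym <- mk(19.8, 20.2)
  expect_equal(unname(ef_distance(asym)$per_chain), c(19.8, 20.2))
  expect_equal(ef_distance(asym)$mean, 20)
  moved <- transform_atoms(asym, 1:4, rot = rotation_matrix(c(1, 1, 0), 33),
                           translation = c(4, 5, 6))
  expect_equal(ef_distance(moved)$mean, 20, tolerance = 1e-10)
  expect_error(ef_distance(st, residues = c(66, 999)), "missing Calpha")
})

test_that("Kabsch superposition recovers exact transforms and beats raw RMSD", {
  set.seed(21)
  X <- matrix(rnorm(150), ncol = 3)
  idfit <- kabsch_superpose(X, X)
  expect_equal(idfit$rmsd, 0, tolerance = 1e-10)
  expect_equal(idfit$rotation, diag(3), tolerance = 1e-10)

  R30 <- rotation_matrix(c(0, 0, 1), 30)
  Y <- X %*% t(R30) + matrix(c(3, -2, 7), nrow(X), 3, byrow = TRUE)
  fit <- kabsch_superpose(X, Y)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit$rotation, R30, tolerance = 1e-10)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-12)

  # with jitter, superposed RMSD <= raw RMSD and the rotation is optimal
  Yj <- Y + matrix(rnorm(length(Y), 0, 0.1), nrow(Y))
  fitj <- kabsch_superpose(X, Yj)
  raw <- sqrt(mean(rowSums((X - Yj)^2)))
  expect_lte(fitj$rmsd, raw)
  expect_error(kabsch_superpose(X[1:2, ], Y[1:2, ]), "3 points")
  line <- cbind(1:10, 0, 0)
  expect_true(kabsch_superpose(line, line)$degenerate)
})

test_that("Kabsch RMSD matches a brute-force rotation-search oracle", {
  set.seed(22)
  X <- matrix(rnorm(150), ncol = 3)
  Y <- X %*% t(rotation_matrix(c(2, -1, 1), 24)) +
    matrix(rnorm(150, 0, 0.1), ncol = 3)
  kb <- kabsch_superpose(X, Y)$rmsd
  # independent numeric optimisation over axis-angle parameters
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Y, 2, colMeans(Y))
  rmsd_of <- function(par) {
    R <- rotation_matrix(c(sin(par[1]) * cos(par[2]),
                           sin(par[1]) * sin(par[2]), cos(par[1])), par[3])
    sqrt(mean(rowSums((Xc %*% t(R) - Yc)^2)))
  }
  best <- Inf
  for (s in 1:20) {
    set.seed(s)
    o <- optim(c(runif(1, 0, pi), runif(1, 0, 2 * pi), runif(1, -180, 180)),
               rmsd_of, control = list(maxit = 2000, reltol = 1e-12))
    best <- min(best, o$value)
  }
  expect_equal(kb, best, tolerance = 1e-3)
  expect_lte(kb, best + 1e-8)
})

test_that("subunit rotation angle measures constructed quaternary rotations", {
  st <- toy_dimer()
  expect_equal(subunit_rotation_angle(st, st), 0, tolerance = 1e-8)
  rot <- transform_atoms(st, which(st$chain == "B"),
                         rot = rotation_matrix(c(1, 1, 2), 5),
                         center = atom_centroid(st, which(st$chain == "B")))
  expect_equal(subunit_rotation_angle(rot, st), 5, tolerance = 1e-6)
  # invariant to global rigid motion of the query
  glob <- transform_atoms(rot, seq_len(nrow(rot)),
                          rot = rotation_matrix(c(1, 0, 3), 71),
                          translation = c(-4, 9, 2))
  expect_equal(subunit_rotation_angle(glob, st), 5, tolerance = 1e-6)
})

test_that("heme-heme distance uses Fe-Fe with a flagged centroid fallback", {
  st <- toy_dimer()
  fe <- which(st$element == "FE")
  d_fe <- sqrt(sum((coords(st, fe[1]) - coords(st, fe[2]))^2))
  hh <- heme_heme_distance(st)
  expect_equal(hh$distance, d_fe)
  expect_false(hh$fallback)
  stripped <- structure_from_atoms(as.data.frame(st)[-fe, ])
  expect_warning(hh2 <- heme_heme_distance(stripped), "centroid")
  expect_true(hh2$fallback)
  heme_a <- which(stripped$resid == "HEM" & stripped$chain == "A")
  heme_b <- which(stripped$resid == "HEM" & stripped$chain == "B")
  expect_equal(hh2$distance,
               sqrt(sum((atom_centroid(stripped, heme_a) -
                           atom_centroid(stripped, heme_b))^2)))
  no_heme <- structure_from_atoms(
    as.data.frame(st)[st$resid != "HEM", ])
  expect_error(heme_heme_distance(no_heme), "2 heme")
})

test_that("ensemble statistics use the population sd and recover the generative angle", {
  base <- toy_dimer()
  rotate_by <- function(ang) {
    transform_atoms(base, which(base$chain == "B"),
                    rot = rotation_matrix(c(1, 0, 0), ang),
                    center = c(0, 0, 0))
  }
  single <- ensemble_statistics(list(rotate_by(3)), list(ref = base))
  expect_equal(single$summary$sd, rep(0, nrow(single$summary)))

  two <- ensemble_statistics(list(rotate_by(3), rotate_by(5)),
                             list(ref = base))
  rot_row <- two$summary[two$summary$descriptor == "rotation_vs_ref", ]
  expect_equal(rot_row$mean, 4, tolerance = 1e-6)
  expect_equal(rot_row$sd, 1, tolerance = 1e-6)
  expect_error(ensemble_statistics(list(), list(ref = base)), "empty")
})
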