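test_that("form factors reproduce atomic numbers at q = 0 and the tabulated Gaussian sum", {
  tab <- form_factor_table()
  for (el in tab$element) {
    expect_equal(effective_form_factor(el, 0), tab$Z[tab$element == el],
                 tolerance = 5e-3)
  }
  # independent evaluation of the 4-Gaussian sum at q = 0.5 for carbon
  row <- tab[tab$element == "C", ]
  s2 <- (0.5 / (4 * pi))^2
  f_direct <- row$c + sum(unlist(row[paste0("a", 1:4)]) *
                            exp(-unlist(row[paste0("b", 1:4)]) * s2))
  expect_equal(effective_form_factor("C", 0.5), f_direct, tolerance = 1e-12)
  # solvent-corrected oxygen at q = 0: f(0) - rho_s * V
  vo <- tab$V[tab$element == "O"]
  expect_equal(effective_form_factor("O", 0, mode = "solvent"),
               effective_form_factor("O", 0) - 0.334 * vo,
               tolerance = 1e-12)
  expect_error(effective_form_factor("XX", 0.3), "supported")
})

test_that("Debye intensity matches closed forms for one and two atoms", {
  q <- seq(0.15, 1, length.out = 30)
  one <- structure_from_atoms(data.frame(element = "C", resno = 1,
                                         chain = "A", x = 0, y = 0, z = 0))
  fC <- effective_form_factor("C", q)
  expect_equal(debye_intensity(one, q)$intensity, fC^2, tolerance = 1e-12)
  d <- 5
  two <- structure_from_atoms(data.frame(element = c("C", "C"), resno = 1:2,
                                         chain = "A", x = c(0, d),
                                         y = 0, z = 0))
  expect_equal(debye_intensity(two, q)$intensity,
               2 * fC^2 * (1 + sin(q * d) / (q * d)), tolerance = 1e-12)
})

test_that("direct Debye equals the brute-force oracle and I(0) = (sum f)^2", {
  st <- random_structure(50)
  q <- seq(0.15, 1, length.out = 25)
  expect_equal(debye_intensity(st, q)$intensity, debye_oracle(st, q),
               tolerance = 1e-9)
  q0 <- 1e-9
  f0 <- sum(vapply(st$element, function(e) effective_form_factor(e, 0),
                   numeric(1)))
  expect_equal(debye_intensity(st, q0)$intensity, f0^2, tolerance = 1e-6)
})

test_that("histogram path tracks the direct sum within the binning tolerance", {
  st <- toy_dimer()
  q <- default_qgrid()
  direct <- debye_intensity(st, q)$intensity
  hist <- debye_intensity(st, q, method = "histogram")$intensity
  expect_lt(max(abs(hist / direct - 1)), 1e-4)
  # finer bins tighten agreement
  hist2 <- debye_intensity(st, q, method = "histogram", bin = 0.02)$intensity
  expect_lt(max(abs(hist2 / direct - 1)), max(abs(hist / direct - 1)))
})

test_that("Debye intensity is invariant under global rotation and translation", {
  st <- random_structure(40, seed = 11)
  q <- seq(0.15, 1, length.out = 25)
  ref <- debye_intensity(st, q)$intensity
  moved <- transform_atoms(st, seq_len(nrow(st)),
                           rot = rotation_matrix(c(1, 2, 3), 47),
                           translation = c(5, -3, 11))
  expect_equal(debye_intensity(moved, q)$intensity, ref, tolerance = 1e-9)
  expect_true(all(ref >= 0))
})

test_that("difference curves are antisymmetric and decompose atom removals", {
  st <- random_structure(50, seed = 3)
  q <- seq(0.15, 1, length.out = 25)
  reduced <- structure_from_atoms(as.data.frame(st)[-17, ])
  ds <- difference_curve(st, reduced, q)
  expect_equal(ds$intensity,
               debye_oracle(st, q) - debye_oracle(reduced, q),
               tolerance = 1e-9)
  expect_equal(difference_curve(reduced, st, q)$intensity, -ds$intensity)
  expect_equal(difference_curve(st, st, q)$intensity, rep(0, length(q)))
})

test_that("attached waters join the host body and move rigidly with it", {
  st <- toy_dimer()
  n0 <- nrow(st)
  wat <- rbind(c(0, 1, 2), c(1, 0, 2))
  st2 <- attach_waters(st, wat, "A:heme")
  expect_equal(nrow(st2), n0 + 2L)
  expect_true(all(st2$body[(n0 + 1):(n0 + 2)] == "A:heme"))
  expect_error(attach_waters(st, wat, "Z:heme"), "host body")

  # rigid transform of the heme body carries its waters along
  idx <- which(st2$body == "A:heme")
  moved <- transform_atoms(st2, idx, rot = rotation_matrix(c(0, 0, 1), 25),
                           translation = c(1, 2, 3))
  d_before <- dist(coords(st2, idx))
  d_after <- dist(coords(moved, idx))
  expect_equal(as.vector(d_after), as.vector(d_before), tolerance = 1e-9)

  # difference with/without waters equals two independent Debye runs
  q <- seq(0.15, 1, length.out = 20)
  ds <- difference_curve(st2, st, q)
  expect_equal(ds$intensity,
               debye_intensity(st2, q)$intensity -
                 debye_intensity(st, q)$intensity, tolerance = 1e-12)
})

test_that("band power ratio handles the degenerate and constructed cases", {
  q <- default_qgrid()
  flat <- scattering_curve(q, rep(1, length(q)))
  same <- band_power_ratio(flat, flat)
  expect_equal(same$ratio, 0)
  expect_true(same$degenerate)

  low_only <- scattering_curve(q, ifelse(q < 0.4, 1, 0) + 1)
  inf_case <- band_power_ratio(low_only, flat)
  expect_equal(inf_case$ratio, Inf)

  # equal per-band RMS by construction -> ratio 1
  both <- scattering_curve(q, 1 + 0.5 * c(rep(1, sum(q < 0.4)),
                                          rep(-1, sum(q >= 0.4))))
  expect_equal(band_power_ratio(both, flat)$ratio, 1)
  expect_error(band_power_ratio(flat, flat, small = c(0.01, 0.05)), "band")
})

test_that("removing interfacial waters expresses itself mostly at small angles", {
  st <- toy_dimer()
  q <- default_qgrid()
  # strip two waters hydrogen-bonded across the interface
  wat_idx <- which(st$is_water)[1:2]
  stripped <- structure_from_atoms(as.data.frame(st)[-wat_idx, ])
  with_w <- debye_intensity(st, q)
  without_w <- debye_intensity(stripped, q)
  bp <- band_power_ratio(with_w, without_w)
  expect_gt(bp$ratio, 1)
})
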