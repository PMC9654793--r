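test_that("12-6 term: well minimum, decay and direct substitution", {
  A <- 1e5; B <- 100
  req <- (2 * A / B)^(1 / 6)
  expect_equal(vdw_term(req, c(A, B)), -B^2 / (4 * A), tolerance = 1e-12)
  expect_lt(abs(vdw_term(3 * req, c(A, B))), 0.01 * B^2 / (4 * A))
  expect_equal(vdw_term(1, c(2, 2)), 0)
  expect_error(vdw_term(0, c(A, B)), "positive")
})

test_that("12-10 term: unit angular weight at ideal, node at 90 degrees off", {
  ang <- PARAMS$angular
  expect_equal(hbond_term(1, 180, c(5, 6), ang), -1)
  expect_equal(hbond_term(2.9, 90, c(5, 6), ang), 0)
  # E decreases monotonically away from ideal
  vals <- sapply(c(180, 150, 120, 95), function(t) hbond_term(3.2, t, c(5e4, 6e3), ang))
  expect_true(all(diff(abs(vals)) < 0))
  expect_error(hbond_term(-1, 180, c(5, 6), ang))
})

test_that("screened Coulomb: sigmoidal dielectric rises to bulk; sign rules hold", {
  d <- PARAMS$dielectric
  expect_true(all(diff(sigmoidal_dielectric(seq(0.5, 60, 0.5), d)) > 0))
  expect_lt(abs(sigmoidal_dielectric(50, d) - 78.4) / 78.4, 0.01)
  expect_equal(elec_term(5, 0, 0.7, d), 0)
  expect_gt(elec_term(3, 0.3, 0.4, d), 0)
  expect_lt(elec_term(3, -0.3, 0.4, d), 0)
  expect_lt(elec_term(12, -0.3, 0.4, d), 0)
})

test_that("torsion penalty is linear and pose-independent", {
  expect_equal(torsion_penalty(0, 0.3113), 0)
  expect_equal(torsion_penalty(3, 0.3113), 0.9339, tolerance = 1e-12)
  expect_equal(torsion_penalty(6, 0.3113), 2 * torsion_penalty(3, 0.3113))
})

test_that("dehydration term: empty sum, full burial clamp, hand-computed value", {
  lig <- data.frame(x = 0, y = 0, z = 0, S = 0.01, occmax = 20,
                    type_code = "C")
  none <- data.frame(x = numeric(), y = numeric(), z = numeric(), V = numeric())
  expect_equal(desolvation_term(lig, none, 3.5, 1), 1 * 0.01 * 20)
  one <- data.frame(x = 3.5, y = 0, z = 0, V = 10)
  expect_equal(desolvation_term(lig, one, 3.5, 1),
               0.01 * (20 - 10 * exp(-0.5)), tolerance = 1e-12)
  # occupancy exactly at occmax -> zero; beyond occmax -> clamped at zero
  buried <- data.frame(x = rep(0.1, 4), y = 0, z = 0, V = 20 / (4 * exp(-0.01 / 24.5)))
  expect_equal(desolvation_term(lig, buried, 3.5, 1), 0, tolerance = 1e-9)
  over <- data.frame(x = rep(0.1, 40), y = 0, z = 0, V = 10)
  expect_equal(desolvation_term(lig, over, 3.5, 1), 0)
  # monotone: adding a neighbor never increases the deficit
  expect_lte(desolvation_term(lig, rbind(one, c(0, 3, 0, 10)), 3.5, 1),
             desolvation_term(lig, one, 3.5, 1))
})

test_that("decomposition is additive and a far ligand scores the torsion penalty only", {
  tc <- make_toy_complex(3, "binder")
  br <- binding_free_energy(tc$receptor, tc$ligand, tc$planted_pose, PARAMS)
  expect_equal(br$total, br$vdw + br$hbond + br$elec + br$torsion + br$desolvation,
               tolerance = 1e-9)
  far <- new_pose(translation = c(500, 500, 500),
                  torsions = rep(0, length(tc$planted_pose$torsions)))
  brf <- binding_free_energy(tc$receptor, tc$ligand, far, PARAMS)
  expect_equal(brf$vdw, 0); expect_equal(brf$hbond, 0); expect_equal(brf$elec, 0)
  expect_equal(brf$total - brf$desolvation,
               torsion_penalty(tc$ligand$n_tor, PARAMS$weights[["tor"]]),
               tolerance = 1e-12)
  # the far ligand keeps only its self-occupancy: fully hydrated cost
  expect_gte(brf$desolvation, 0)
})

test_that("single neutral probe at the pair minimum scores the weighted well depth", {
  p <- default_parameters(weights = c(vdw = 0.1485, hbond = 0.0656, elec = 0.1146,
                                      tor = 0.3113, sol = 0))
  rec <- single_atom_receptor(p)
  probe <- assign_atom_types(molecule(
    data.frame(element = "C", x = 4.0, y = 0, z = 0), NULL, "probe"), p)
  br <- binding_free_energy(rec, probe, NULL, p)
  expect_equal(br$total, -0.1485 * 0.150, tolerance = 1e-9)
})

test_that("rigid transforms of receptor and pose leave every term unchanged", {
  tc <- make_toy_complex(4, "binder")
  base <- binding_free_energy(tc$receptor, tc$ligand, tc$planted_pose, PARAMS)
  g <- hingedock:::quat_from_axis_angle(c(1, 2, -0.5), 73)
  moved <- transform_complex(tc$receptor, tc$planted_pose, g, c(3.2, -7.1, 11))
  after <- binding_free_energy(moved$rec, tc$ligand, moved$pose, PARAMS)
  for (term in c("vdw", "hbond", "elec", "torsion", "desolvation", "total")) {
    expect_lt(abs(base[[term]] - after[[term]]), 1e-9)
  }
})

test_that("production scorer matches the brute-force oracle on planted and perturbed poses", {
  for (s in 1:6) {
    tc <- make_toy_complex(s, if (s %% 2) "binder" else "nonbinder")
    d <- abs(binding_free_energy(tc$receptor, tc$ligand, tc$planted_pose, PARAMS)$total -
             tc$expected$total)
    expect_lt(d, 1e-9)
    # a random perturbed pose, same agreement
    po <- hingedock:::with_seed(s, function() new_pose(
      translation = tc$planted_pose$translation + stats::rnorm(3, 0, 0.8),
      orientation = hingedock:::random_unit_quat(),
      torsions = tc$planted_pose$torsions))
    d2 <- abs(binding_free_energy(tc$receptor, tc$ligand, po, PARAMS)$total -
              brute_force_energy(tc$receptor, tc$ligand, po, PARAMS)$total)
    expect_lt(d2, 1e-9)
  }
  # hard-clash geometries agree to relative precision (their r^-12 walls are
  # astronomically steep, so absolute agreement is precision-limited)
  tc <- make_toy_complex(2, "clash")
  sc <- binding_free_energy(tc$receptor, tc$ligand, tc$planted_pose, PARAMS)
  expect_true(sc$clash)
  expect_lt(abs(sc$total - tc$expected$total) / abs(tc$expected$total), 1e-9)
})

test_that("disabling the dehydration term reproduces a pure 4-term score", {
  tc <- make_toy_complex(7, "binder")
  p4 <- PARAMS
  p4$use_solvation <- FALSE
  p4$weights[["sol"]] <- 0
  b4 <- binding_free_energy(tc$receptor, tc$ligand, tc$planted_pose, p4)
  expect_equal(b4$desolvation, 0)
  b5 <- binding_free_energy(tc$receptor, tc$ligand, tc$planted_pose, PARAMS)
  expect_equal(b4$vdw, b5$vdw, tolerance = 1e-12)
  expect_equal(b4$hbond, b5$hbond, tolerance = 1e-12)
  expect_equal(b4$elec, b5$elec, tolerance = 1e-12)
  expect_equal(b4$total, b5$total - b5$desolvation, tolerance = 1e-9)
})
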