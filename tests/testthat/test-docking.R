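toy_grids <- function(tc, spacing = 0.375, extent = 11) {
  build_grids(tc$receptor, grid_box(c(-1, 0.2, 0), extent, spacing), PARAMS,
              types = unique(tc$ligand$atoms$type_code))
}

test_that("a probe evaluated on a grid node equals the direct pair sum", {
  tc <- make_toy_complex(1, "binder")
  g <- toy_grids(tc)
  # single neutral probe atom placed exactly on a node
  node <- g$origin + g$spacing * c(12, 14, 13)
  probe <- assign_atom_types(molecule(
    data.frame(element = "C", x = node[1], y = node[2], z = node[3]),
    NULL, "probe"), PARAMS)
  ge <- grid_energy(g, probe, NULL, PARAMS)
  bf <- binding_free_energy(tc$receptor, probe, NULL, PARAMS)
  expect_equal(ge$vdw, bf$vdw, tolerance = 1e-9)
  expect_equal(ge$desolvation, bf$desolvation, tolerance = 1e-9)
})

test_that("trilinear interpolation is exact on nodes and linear along edges", {
  # handcrafted single linear map f(x,y,z) = 2x - y + 3z + 1
  dims <- c(5L, 5L, 5L)
  origin <- c(0, 0, 0); spacing <- 1
  ax <- lapply(1:3, function(k) origin[k] + (0:4) * spacing)
  grid <- expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]])
  f <- array(2 * grid$x - grid$y + 3 * grid$z + 1, dim = dims)
  pts <- rbind(c(2, 3, 1),          # node
               c(2.5, 3, 1),        # edge midpoint
               c(1.3, 2.7, 3.9))    # interior
  got <- hingedock:::trilinear(f, origin, spacing, dims, pts)
  expect_equal(got, 2 * pts[, 1] - pts[, 2] + 3 * pts[, 3] + 1, tolerance = 1e-12)
})

test_that("electrostatic map scales linearly with probe charge", {
  tc <- make_toy_complex(2, "binder")
  g <- toy_grids(tc)
  at <- data.frame(element = "C", x = -1.2, y = 0.4, z = 0.2)
  p1 <- assign_atom_types(molecule(at, NULL, "q1"), PARAMS); p1$atoms$charge <- 0.25
  p2 <- p1; p2$atoms$charge <- 0.5
  e1 <- grid_energy(g, p1, NULL, PARAMS)$elec
  e2 <- grid_energy(g, p2, NULL, PARAMS)$elec
  expect_equal(e2, 2 * e1, tolerance = 1e-9)
})

test_that("grid and direct scores converge as spacing shrinks", {
  tc <- make_toy_complex(1, "binder")
  direct <- binding_free_energy(tc$receptor, tc$ligand, tc$planted_pose, PARAMS)$total
  errs <- vapply(c(1.0, 0.5, 0.25), function(sp) {
    abs(grid_energy(toy_grids(tc, sp, extent = 12), tc$ligand, tc$planted_pose,
                    PARAMS)$total - direct)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 0.1)
})

test_that("poses outside the box are rejected with an infinite score", {
  tc <- make_toy_complex(1, "binder")
  g <- toy_grids(tc)
  out <- new_pose(translation = c(100, 0, 0),
                  torsions = rep(0, length(tc$planted_pose$torsions)))
  expect_true(is.infinite(grid_energy(g, tc$ligand, out, PARAMS)$total))
  expect_error(grid_energy(g, tc$ligand, out, PARAMS, outside = "error"), "outside")
})

test_that("docking is seed-deterministic and monotone in the number of runs", {
  tc <- make_toy_complex(1, "binder")
  g <- toy_grids(tc)
  cfg <- dock_config(pop_size = 10, n_gens = 6, local_steps = 10)
  a <- dock(tc$ligand, g, tc$receptor, PARAMS, n_runs = 4, seed = 5, search_cfg = cfg)
  b <- dock(tc$ligand, g, tc$receptor, PARAMS, n_runs = 4, seed = 5, search_cfg = cfg)
  expect_identical(a$energies, b$energies)
  expect_identical(a$best$translation, b$best$translation)
  # runs are seeded from (seed, run index): more runs minimize over a superset
  c8 <- dock(tc$ligand, g, tc$receptor, PARAMS, n_runs = 8, seed = 5, search_cfg = cfg)
  expect_identical(c8$energies[1:4], a$energies)
  expect_lte(c8$best$score$total, a$best$score$total)
  expect_error(dock(tc$ligand, g, tc$receptor, PARAMS, n_runs = 0), "n_runs")
  # clusters partition the poses
  members <- sort(unlist(lapply(c8$clusters, `[[`, "members")))
  expect_identical(members, seq_along(c8$poses))
})

test_that("pose RMSD is zero for identical poses, exact for translations, symmetry-aware", {
  bz <- build_torsion_tree(mol_benzene())
  p0 <- identity_pose(bz)
  expect_equal(pose_rmsd(bz, p0, p0), 0)
  p1 <- new_pose(translation = p0$translation + c(1, 0, 0))
  expect_equal(pose_rmsd(bz, p0, p1), 1.0, tolerance = 1e-9)
  # 180-degree in-plane flip maps the ring onto itself
  flip <- new_pose(translation = p0$translation,
                   orientation = hingedock:::quat_from_axis_angle(c(0, 0, 1), 60))
  expect_lt(pose_rmsd(bz, p0, flip), 1e-6)
  bu <- build_torsion_tree(mol_butane())
  expect_error(pose_rmsd(bu, identity_pose(bu), p0), "torsion")
})
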