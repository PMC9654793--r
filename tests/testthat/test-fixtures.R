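test_that("toy complexes are pure in their seed and satisfy their planted contracts", {
  a <- make_toy_complex(9, "binder")
  b <- make_toy_complex(9, "binder")
  expect_identical(coords(a$ligand), coords(b$ligand))
  expect_identical(a$expected$total, b$expected$total)
  expect_identical(as.matrix(a$receptor$atoms[, c("x", "y", "z")]),
                   as.matrix(b$receptor$atoms[, c("x", "y", "z")]))

  expect_true(hinge_hbond_check(a$ligand, a$planted_pose, a$receptor)$pass)
  nb <- make_toy_complex(9, "nonbinder")
  expect_false(hinge_hbond_check(nb$ligand, nb$planted_pose, nb$receptor)$pass)
  cl <- make_toy_complex(9, "clash")
  expect_true(binding_free_energy(cl$receptor, cl$ligand, cl$planted_pose,
                                  PARAMS)$clash)
  # the expected breakdown is the oracle's own re-evaluation
  expect_identical(a$expected$total,
                   brute_force_energy(a$receptor, a$ligand, a$planted_pose,
                                      PARAMS)$total)
})

test_that("the planted binder pose is a local optimum of the score", {
  tc <- make_toy_complex(1, "binder")
  e0 <- binding_free_energy(tc$receptor, tc$ligand, tc$planted_pose, PARAMS)$total
  worse <- hingedock:::with_seed(42, function() {
    vapply(1:20, function(i) {
      po <- new_pose(translation = tc$planted_pose$translation + stats::rnorm(3, 0, 1.2),
                     orientation = hingedock:::random_unit_quat(),
                     torsions = tc$planted_pose$torsions)
      binding_free_energy(tc$receptor, tc$ligand, po, PARAMS)$total
    }, numeric(1))
  })
  expect_true(mean(worse > e0) >= 0.9)
})

test_that("labeled libraries hit the requested composition reproducibly", {
  l0 <- make_library(2, 0)
  expect_length(l0$molecules, 0)
  lib <- make_library(2, 200, 0.1)
  expect_length(lib$molecules, 200)
  expect_equal(sum(lib$labels$binder), 20)
  expect_gt(sum(!lib$labels$ro5_expected), 0)
  lib2 <- make_library(2, 200, 0.1)
  expect_identical(lib$labels, lib2$labels)
  expect_identical(coords(lib$molecules[[5]]), coords(lib2$molecules[[5]]))
  # binders carry a polar acceptor; nonbinders are carbon-only
  for (k in c(1, 50, 200)) {
    m <- lib$molecules[[k]]
    has_polar <- any(m$atoms$element %in% c("N", "O"))
    expect_identical(has_polar, lib$labels$binder[k])
  }
  # the declared druggability failures break >= 2 rules
  fail_id <- lib$labels$id[!lib$labels$ro5_expected][1]
  v <- rule_of_five(lib$molecules[[which(lib$labels$id == fail_id)]])
  expect_false(v$passed)
  expect_gte(length(v$violations), 2)
})

test_that("fixture sets round-trip through their plain-text formats", {
  dir <- tempfile()
  write_fixture_set(dir, seed = 3, n_library = 6)
  rec <- load_receptor(file.path(dir, "toy_receptor_synthetic.pdb"))
  expect_gt(nrow(rec$atoms), 20)
  expect_true(1950 %in% rec$atoms$resno)
  mols <- load_library(file.path(dir, "toy_library_synthetic.sdf"))
  expect_length(mols, 6)
  labels <- utils::read.delim(file.path(dir, "toy_library_labels.tsv"))
  expect_equal(nrow(labels), 6)
})
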