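two_site_core <- function() {
  m <- molecule(data.frame(element = c("O", "C", "C", "H", "H"),
                           x = c(-1.93, -0.81, -0.2, -0.4, 0.88),
                           y = c(0.2, 0.15, 1.4, -0.78, 1.35),
                           z = c(0, 0, 0.1, -0.05, 0.12)),
                data.frame(i = c(1, 2, 3, 3), j = c(2, 3, 4, 5),
                           order = c(2, 1, 1, 1)), "core")
  core_template(m, data.frame(heavy = c(3, 3), hydrogen = c(4, 5)))
}

test_that("derivative enumeration is the deduplicated Cartesian product", {
  ct <- two_site_core()
  # 1 site x {H, CH3} -> 2 derivatives
  ct1 <- core_template(ct$molecule, data.frame(heavy = 3, hydrogen = 4))
  d1 <- enumerate_derivatives(ct1, fragments_per_site = c("H", "methyl"))
  expect_length(d1, 2)
  # the two sites share a carbon, so assignments are symmetric:
  # 5^2 = 25 combinations collapse to choose(6, 2) = 15 unique structures
  d2 <- enumerate_derivatives(ct, fragments_per_site = c("H", "methyl", "ethyl",
                                                         "methoxy", "chloro"))
  expect_length(d2, 15)
  expect_equal(attr(d2, "n_duplicates"), 10L)
  # the all-H derivative reproduces the core exactly
  allh <- Filter(function(d) all(attr(d, "rgroups") == "H"), d2)[[1]]
  expect_equal(coords(allh), coords(ct$molecule), tolerance = 0)
  expect_error(enumerate_derivatives(ct, fragments_per_site = c("methyl")), "'H'")
  expect_error(enumerate_derivatives(ct, max_enum = 3,
                                     fragments_per_site = c("H", "methyl")),
               "max_enum")
})

test_that("growth keeps the core frozen and the all-H derivative scores as the core", {
  tc <- make_toy_complex(1, "binder")
  ct <- two_site_core()
  der <- enumerate_derivatives(ct, fragments_per_site = c("H", "methyl", "chloro"))
  ranked <- grow_and_score(ct, der, tc$receptor, NULL, PARAMS, n_scan = 6)
  expect_equal(ranked$rank, seq_len(nrow(ranked)))
  expect_true(!is.unsorted(ranked$total))
  mols <- attr(ranked, "molecules")
  core_xyz <- coords(ct$molecule)
  for (id in ranked$id) {
    d <- mols[[id]]
    ci <- attr(d, "core_atoms")
    co <- attr(d, "core_orig")
    expect_equal(max(abs(coords(d)[ci, , drop = FALSE] -
                         core_xyz[co, , drop = FALSE])), 0)
  }
  core_scored <- assign_atom_types(gasteiger_charges(ct$molecule), PARAMS)
  e_core <- binding_free_energy(tc$receptor, core_scored, NULL, PARAMS)$total
  e_allh <- ranked$total[ranked$id == "core[H,H]"]
  expect_identical(unname(e_allh), e_core)
})

test_that("derivative ranking is independent of enumeration order", {
  tc <- make_toy_complex(1, "binder")
  ct <- two_site_core()
  der <- enumerate_derivatives(ct, fragments_per_site = c("H", "methyl", "chloro"))
  r1 <- grow_and_score(ct, der, tc$receptor, NULL, PARAMS, n_scan = 4)
  r2 <- grow_and_score(ct, rev(der), tc$receptor, NULL, PARAMS, n_scan = 4)
  expect_equal(r1$id, r2$id)
  expect_equal(r1$total, r2$total, tolerance = 1e-12)
})

test_that("candidate selection applies the druggability filter then truncates", {
  tc <- make_toy_complex(1, "binder")
  ct <- two_site_core()
  der <- enumerate_derivatives(ct, fragments_per_site = c("H", "methyl"))
  ranked <- grow_and_score(ct, der, tc$receptor, NULL, PARAMS, n_scan = 4)
  all_sel <- select_candidates(ranked, 100, PARAMS)
  expect_lte(nrow(all_sel), nrow(ranked))
  one <- select_candidates(ranked, 1, PARAMS)
  expect_equal(nrow(one), 1)
  expect_equal(one$id, all_sel$id[1])
  expect_error(select_candidates(ranked, 0), "positive")
  # no selected molecule breaks 2+ Rule-of-Five rules
  for (id in all_sel$id) {
    v <- rule_of_five(attr(all_sel, "molecules")[[id]], PARAMS)
    expect_true(v$passed)
  }
})

test_that("a polar substituent pays a higher dehydration cost on binding than a nonpolar one", {
  # bind = pocket pose; unbound reference = same conformer far from the
  # receptor; the dehydration term should penalize burying the methoxy
  # oxygen more than burying a methyl of similar size
  tc <- make_toy_complex(1, "binder")
  ct <- two_site_core()
  der <- enumerate_derivatives(ct, fragments_per_site = c("H", "methyl", "methoxy"))
  ranked <- grow_and_score(ct, der, tc$receptor, NULL, PARAMS, n_scan = 8)
  mols <- attr(ranked, "molecules")
  dd_sol <- function(rgroup) {
    id <- ranked$id[ranked$R1 == rgroup & ranked$R2 == "H"]
    m <- mols[[id]]
    far <- new_pose(translation = c(500, 500, 500),
                    torsions = rep(0, length(m$torsion_tree$branches)))
    binding_free_energy(tc$receptor, m, NULL, PARAMS)$desolvation -
      binding_free_energy(tc$receptor, m, far, PARAMS)$desolvation
  }
  expect_gt(dd_sol("methoxy"), dd_sol("methyl"))
})
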