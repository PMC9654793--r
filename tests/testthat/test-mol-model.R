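test_that("SDF library loading honors file order and skips malformed records", {
  tmp <- tempfile(fileext = ".sdf")
  write_sdf(list(mol_water(), mol_benzene()), tmp)
  # append a malformed record
  cat("broken\n  x\n\nnot a counts line\nM  END\n$$$$\n",
      file = tmp, append = TRUE)
  mols <- suppressMessages(load_library(tmp))
  expect_length(mols, 2)
  expect_equal(attr(mols, "skipped"), 1L)
  expect_equal(mols[[1]]$name, "water")
  expect_equal(sum(mols[[2]]$atoms$element != "H"), 6)
  expect_equal(count_rotatable_bonds(mols[[2]]), 0)

  empty <- tempfile(fileext = ".sdf")
  file.create(empty)
  expect_warning(out <- load_library(empty), "no valid records")
  expect_length(out, 0)
  expect_error(load_library(tempfile(fileext = ".sdf")), "cannot read")
})

test_that("molecular weight uses standard masses, completes implicit H, and is additive", {
  expect_equal(molecular_weight(mol_water()), 18.015, tolerance = 1e-3)
  carbon <- molecule(data.frame(element = "C", x = 0, y = 0, z = 0), NULL, "CH4")
  expect_equal(molecular_weight(carbon), 12.011 + 4 * 1.008, tolerance = 1e-6)
  # additivity over disconnected fragments
  both <- molecule(rbind(mol_water()$atoms[, c("element", "x", "y", "z")],
                         within(mol_water()$atoms[, c("element", "x", "y", "z")],
                                x <- x + 50)),
                   data.frame(i = c(1, 1, 4, 4), j = c(2, 3, 5, 6), order = 1),
                   "two-waters")
  expect_equal(molecular_weight(both), 2 * molecular_weight(mol_water()),
               tolerance = 1e-9)
  bad <- molecule(data.frame(element = c("C", "Xx"), x = 0:1, y = 0, z = 0),
                  data.frame(i = 1, j = 2, order = 1), "bad")
  expect_error(molecular_weight(bad), "atom index 2")
})

test_that("scaffold compound descriptors match its formula C16H13N3O2", {
  mol <- load_library(extdata("inhibitor2_scaffold.sdf"))[[1]]
  expect_equal(molecular_weight(mol), 279.3, tolerance = 0.05)
  v <- rule_of_five(mol)
  expect_true(v$passed)
  expect_equal(unname(v$descriptor_values["HBD"]), 4)
  expect_equal(unname(v$descriptor_values["HBA"]), 5)
})

test_that("PEOE charges conserve charge and respect symmetry and electronegativity", {
  eth <- molecule(data.frame(element = c("C", "C", rep("H", 6)),
                             x = c(0, 1.54, -0.5, -0.5, -0.5, 2.04, 2.04, 2.04),
                             y = c(0, 0, 0.9, -0.9, 0, 0.9, -0.9, 0),
                             z = c(0, 0, 0, 0, 1, 0, 0, -1)),
                  data.frame(i = c(1, 1, 1, 1, 2, 2, 2), j = c(2, 3, 4, 5, 6, 7, 8),
                             order = 1), "ethane")
  eth <- gasteiger_charges(eth)
  expect_lt(abs(sum(eth$atoms$charge)), 1e-6)
  expect_lt(abs(eth$atoms$charge[1] - eth$atoms$charge[2]), 1e-6)

  meo <- gasteiger_charges(mol_methanol())
  expect_lt(abs(sum(meo$atoms$charge)), 1e-6)
  expect_lt(meo$atoms$charge[2], meo$atoms$charge[1])  # O more negative than C

  # graph-automorphic atoms get identical charges: benzene ring carbons
  bz <- gasteiger_charges(mol_benzene())
  expect_lt(diff(range(bz$atoms$charge)), 1e-6)

  bad <- molecule(data.frame(element = c("C", "Zn"), x = 0:1, y = 0, z = 0),
                  data.frame(i = 1, j = 2, order = 1), "organozinc")
  expect_error(gasteiger_charges(bad), "Zn")
})

test_that("rotatable bond counting follows the docking dialect", {
  expect_equal(count_rotatable_bonds(mol_benzene()), 0)
  expect_equal(count_rotatable_bonds(mol_butane()), 1)
  expect_equal(count_rotatable_bonds(mol_ethylbenzene()), 1)
  # invariant under atom reindexing
  bu <- mol_butane()
  perm <- c(3, 1, 4, 2)
  inv <- order(perm)
  bu2 <- molecule(bu$atoms[perm, ], data.frame(i = inv[bu$bonds$i],
                                               j = inv[bu$bonds$j], order = 1),
                  "butane-perm")
  expect_equal(count_rotatable_bonds(bu2), 1)
  # polar-H rotors counted by default, excluded on request
  meo <- mol_methanol()
  expect_equal(count_rotatable_bonds(meo), 1)     # the O-H rotor
  expect_equal(count_rotatable_bonds(meo, count_polar_h = FALSE), 0)
  # amide exclusion: N-ethylpropionamide heavy skeleton
  # rotors: C2-C3 and N5-C6; C3-N5 is the amide; chain-terminal bonds excluded
  amide <- molecule(data.frame(element = c("C", "C", "C", "O", "N", "C", "C"),
                               x = c(-2.9, -1.5, 0, 0.6, 0.7, 2.15, 2.9),
                               y = c(1.1, 0.3, 0, 1.1, -1.2, -1.4, -2.7), z = 0),
                    data.frame(i = c(1, 2, 3, 3, 5, 6), j = c(2, 3, 4, 5, 6, 7),
                               order = c(1, 1, 2, 1, 1, 1)), "amide")
  expect_equal(count_rotatable_bonds(amide), 2)
})

test_that("Rule-of-Five verdicts use the <=1 violation convention and are monotone", {
  expect_true(rule_of_five(mol_water())$passed)
  # an oversized greasy hydrocarbon breaks both the MW and logP rules
  big <- molecule(data.frame(element = "C", x = 1.53 * (1:42),
                             y = 0.4 * ((1:42) %% 2), z = 0),
                  data.frame(i = 1:41, j = 2:42, order = 1), "C42")
  v <- rule_of_five(big)
  expect_false(v$passed)
  expect_gte(length(v$violations), 2)
  # a single violation still passes
  hex <- molecule(data.frame(element = "C", x = 1.53 * (1:12), y = 0.2 * (1:12) %% 2,
                             z = 0),
                  data.frame(i = 1:11, j = 2:12, order = 1), "C12")
  v12 <- rule_of_five(hex)
  expect_lte(length(v12$violations), 1)
  expect_true(v12$passed)
})

test_that("atom typing assigns roles and solvation parameters", {
  m <- assign_atom_types(gasteiger_charges(mol_methanol()), PARAMS)
  expect_equal(m$atoms$hbond_role[2], "donor-acceptor")       # hydroxyl O
  expect_equal(m$atoms$hbond_role[6], "polar-hydrogen")       # its H
  expect_equal(m$atoms$hbond_role[1], "none")                 # aliphatic C
  expect_false(anyNA(m$atoms$S))
  expect_true(all(m$atoms$V >= 0) && all(m$atoms$occmax > 0))
  # carbonyl oxygen is an acceptor
  ket <- assign_atom_types(molecule(
    data.frame(element = c("O", "C", "C", "C"),
               x = c(0, 1.23, 2, 2), y = c(0, 0, 1.2, -1.2), z = 0),
    data.frame(i = c(1, 2, 2), j = c(2, 3, 4), order = c(2, 1, 1)), "ketone"))
  expect_equal(ket$atoms$hbond_role[1], "acceptor")
})
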