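# residue templates used to build in-memory receptors for the protonation
# and hydrogen-placement rules
asp_residue <- function(shift = c(0, 0, 0), resno = 1L) {
  data.frame(
    element = c("N", "C", "C", "O", "C", "C", "O", "O"),
    name = c("N", "CA", "C", "O", "CB", "CG", "OD1", "OD2"),
    resname = "ASP", resno = resno, chain = "A",
    x = c(0, 1.45, 2.2, 1.7, 1.9, 3.0, 4.2, 2.6) + shift[1],
    y = c(0, 0.2, 1.4, 2.45, -1.1, -1.9, -1.6, -3.05) + shift[2],
    z = 0 + shift[3], stringsAsFactors = FALSE)
}

lys_residue <- function(shift = c(0, 0, 0), resno = 1L) {
  data.frame(
    element = c("N", "C", "C", "O", "C", "C", "C", "C", "N"),
    name = c("N", "CA", "C", "O", "CB", "CG", "CD", "CE", "NZ"),
    resname = "LYS", resno = resno, chain = "A",
    x = c(0, 1.45, 2.2, 1.7, 1.9, 1.3, 2.0, 1.4, 2.1) + shift[1],
    y = c(0, 0.2, 1.4, 2.45, -1.1, -2.4, -3.6, -4.9, -6.1) + shift[2],
    z = 0 + shift[3], stringsAsFactors = FALSE)
}

gly_residue <- function(resno = 1L) {
  data.frame(element = c("N", "C", "C", "O"),
             name = c("N", "CA", "C", "O"),
             resname = "GLY", resno = resno, chain = "A",
             x = c(0, 1.45, 2.2, 1.7), y = c(0, 0.2, 1.4, 2.45), z = 0,
             stringsAsFactors = FALSE)
}

# a lone acceptor oxygen at a given distance from a reference point
acceptor_probe <- function(at) {
  data.frame(element = "O", name = "O", resname = "HOH2", resno = 99L,
             chain = "A", x = at[1], y = at[2], z = at[3],
             stringsAsFactors = FALSE)
}

test_that("PDB loading counts residues, resolves altlocs, rejects empty files", {
  rec <- load_receptor(extdata("tripeptide_synthetic.pdb"))
  expect_s3_class(rec, "Receptor")
  expect_equal(nrow(rec$residues), 3)
  expect_true(all(c("ALA", "GLU", "LYS") %in% rec$residues$resname))

  # altloc: A at occupancy 0.6 retained over B at 0.4
  tmp <- tempfile(fileext = ".pdb")
  writeLines(c(
    sprintf("ATOM      1  N  AALA A   1       0.000   0.000   0.000  0.60  0.00           N"),
    sprintf("ATOM      2  N  BALA A   1       9.000   0.000   0.000  0.40  0.00           N"),
    sprintf("ATOM      3  CA  ALA A   1       1.450   0.200   0.000  1.00  0.00           C"),
    "END"), tmp)
  r2 <- load_receptor(tmp)
  expect_equal(sum(r2$atoms$name == "N"), 1)
  expect_equal(r2$atoms$x[r2$atoms$name == "N"], 0.0)

  bad <- tempfile(fileext = ".pdb")
  file.create(bad)
  expect_error(load_receptor(bad))
})

test_that("Asp is neutral iff an acceptor sits within the 3.5 A limit", {
  asp <- asp_residue()
  od2 <- as.numeric(asp[asp$name == "OD2", c("x", "y", "z")])
  near <- hingedock:::new_receptor(rbind(asp, acceptor_probe(od2 + c(0, -3.4, 0))))
  near <- assign_protonation_states(near)
  expect_equal(near$protonation$state[near$protonation$resname == "ASP"], "neutral")

  far <- hingedock:::new_receptor(rbind(asp, acceptor_probe(od2 + c(0, -3.6, 0))))
  far <- assign_protonation_states(far)
  expect_equal(far$protonation$state[far$protonation$resname == "ASP"], "charged")
  expect_equal(receptor_formal_charge(far), -1L)
})

test_that("Lys is charged without a nearby donor; assignment is idempotent and rigid-motion invariant", {
  rec <- hingedock:::new_receptor(lys_residue())
  rec <- assign_protonation_states(rec)
  expect_equal(rec$protonation$state[rec$protonation$resname == "LYS"], "charged")
  expect_equal(receptor_formal_charge(rec), 1L)
  # idempotent
  again <- assign_protonation_states(rec)
  expect_identical(rec$protonation, again$protonation)
  # invariant under rigid motion
  rot <- lys_residue()
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3, TRUE)
  xyz <- as.matrix(rot[, c("x", "y", "z")]) %*% t(R)
  rot[, c("x", "y", "z")] <- sweep(xyz, 2, c(5, -2, 1), "+")
  rec2 <- assign_protonation_states(hingedock:::new_receptor(rot))
  expect_identical(rec$protonation$state, rec2$protonation$state)
})

test_that("hydrogens are added per assigned protonation state at ideal geometry", {
  # neutral Asp (acceptor planted near OD2) gains the carboxyl H
  asp <- asp_residue()
  od2 <- as.numeric(asp[asp$name == "OD2", c("x", "y", "z")])
  rec <- hingedock:::new_receptor(rbind(asp, acceptor_probe(od2 + c(0, -3.2, 0))))
  rec <- add_hydrogens(assign_protonation_states(rec))
  asp_h <- rec$atoms$element == "H" & rec$atoms$resname == "ASP"
  expect_equal(sum(rec$atoms$name[asp_h] == "HOD2"), 1)

  # charged Lys amine carries 3 H
  recl <- add_hydrogens(assign_protonation_states(
    hingedock:::new_receptor(lys_residue())))
  expect_equal(sum(recl$atoms$name == "HNZ"), 3)
  hnz <- recl$atoms[recl$atoms$name == "HNZ", c("x", "y", "z")]
  nz <- recl$atoms[recl$atoms$name == "NZ", c("x", "y", "z")]
  d <- sqrt(rowSums(sweep(as.matrix(hnz), 2, as.numeric(nz))^2))
  expect_true(all(abs(d - 1.01) < 1e-6))

  # glycine backbone gains 2 H-alpha
  recg <- add_hydrogens(assign_protonation_states(
    hingedock:::new_receptor(gly_residue())))
  expect_equal(sum(recg$atoms$name == "HCA"), 2)
})

test_that("hinge designation caches backbone handles and validates input", {
  rec <- load_receptor(extdata("tripeptide_synthetic.pdb"))
  rec <- designate_hinge_residue(rec, "A", 2)
  expect_equal(rec$atoms$name[rec$hinge$N], "N")
  expect_equal(rec$atoms$name[rec$hinge$O], "O")
  expect_error(designate_hinge_residue(rec, "A", 42), "not found")
  # residue lacking backbone O
  broken <- rec
  broken$atoms <- broken$atoms[!(broken$atoms$resno == 2 & broken$atoms$name == "O"), ]
  broken$residues <- hingedock:::index_residues(broken$atoms)
  expect_error(designate_hinge_residue(broken, "A", 2), "backbone atom O")
})

test_that("full receptor preparation types, charges and stays charge-consistent", {
  rec <- prepare_receptor(extdata("tripeptide_synthetic.pdb"), hinge = c("A", 2))
  expect_false(anyNA(rec$atoms$type_code))
  expect_false(anyNA(rec$atoms$S))
  # PEOE conserves the total formal charge implied by protonation states
  expect_equal(sum(rec$atoms$charge), receptor_formal_charge(rec), tolerance = 1e-6)
  out <- tempfile(fileext = ".pdb")
  write_receptor_pdb(rec, out)
  txt <- readLines(out)
  expect_true(any(grepl("^REMARK   6 .*(charged|neutral)", txt)))
})
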