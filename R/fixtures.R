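# Synthetic-data generators: abstract toy binding pockets with a minimal
# backbone-amide "hinge" motif, planted ligand poses with oracle-computed
# energies, and labeled screening libraries. Everything is pure in its seed,
# so every other module is testable without external data. Toy receptors are
# abstract atom arrangements, not real proteins.

# deterministic quasi-uniform sphere directions (Fibonacci lattice)
#' @noRd
fib_sphere <- function(n) {
  k <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * k / n)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Build a synthetic binding pocket with a hinge amide
#'
#' A shell of nonpolar carbon atoms (radius ~5.3 A around the origin) with a
#' cone-shaped opening toward a single backbone-like amide unit (residue
#' "ALA 1950": N-H donor and C=O acceptor pointing into the cavity). The
#' pocket is deterministic per seed (small positional jitter and shell-size
#' variation). Atom types, solvation parameters and fixed point charges are
#' assigned; the hinge residue is designated.
#'
#' @param seed integer seed.
#' @param n_shell approximate shell atom count (20-60 total atoms).
#' @param params a `ParameterSet`.
#' @return a prepared `Receptor`.
#' @export
make_toy_receptor <- function(seed = 1, n_shell = 36,
                              params = default_parameters()) {
  with_seed(seed * 7 + 13, function() {
    n_shell <- n_shell + sample.int(5, 1) - 3
    shell_dir <- fib_sphere(n_shell)
    # open a cone toward -x where the amide sits
    keep <- shell_dir[, 1] > -0.75
    shell <- shell_dir[keep, , drop = FALSE] * 5.3
    shell <- shell + matrix(stats::rnorm(length(shell), 0, 0.12), ncol = 3)
    # amide unit: N-H donor and C=O acceptor flanking the -x opening
    N <- c(-4.6, 1.35, 0)
    u_nh <- unit3(c(1, -0.42, 0))
    H <- N + 1.01 * u_nh
    CA <- N + 1.45 * unit3(c(-0.75, 0.62, 0.21))
    C <- CA + 1.52 * unit3(c(0.05, -1, -0.1))
    O <- C + 1.23 * unit3(c(1, -0.35, 0.05))
    amide <- rbind(N, H, CA, C, O)
    atoms <- data.frame(
      element = c("N", "H", "C", "C", "O", rep("C", nrow(shell))),
      name = c("N", "H", "CA", "C", "O", sprintf("P%02d", seq_len(nrow(shell)))),
      resname = c(rep("ALA", 5), rep("POC", nrow(shell))),
      resno = c(rep(1950L, 5), rep(1L, nrow(shell))),
      chain = "A",
      x = c(amide[, 1], shell[, 1]),
      y = c(amide[, 2], shell[, 2]),
      z = c(amide[, 3], shell[, 3]),
      stringsAsFactors = FALSE)
    rec <- new_receptor(atoms)
    rec$atoms <- type_atoms_impl(rec$atoms, rec$bonds,
                                 rep(FALSE, nrow(rec$atoms)), params)
    # fixed amide charges; shell carbons neutral
    rec$atoms$charge <- c(-0.35, 0.25, 0.10, 0.45, -0.45, rep(0, nrow(shell)))
    rec$polar <- receptor_polar_geometry(rec)
    rec$protonation <- data.frame(
      chain = character(), resno = integer(), resname = character(),
      state = character(), tautomer = character(), reason = character())
    designate_hinge_residue(rec, "A", 1950L)
  })
}

# small rigid ketone-like probe: O double-bonded to a trigonal carbon with
# two methyl-like heavy neighbors (n_tor = 0)
#' @noRd
make_probe_ligand <- function(o_pos, toward, name = "probe", jitter = 0) {
  u <- unit3(toward)
  c1 <- o_pos + 1.23 * u
  e <- any_perp(u); f <- unit3(cross3(u, e))
  c2 <- c1 + 1.50 * unit3(u * cos(2 * pi / 3) + e * sin(2 * pi / 3))
  c3 <- c1 + 1.50 * unit3(u * cos(2 * pi / 3) - e * sin(2 * pi / 3))
  xyz <- rbind(o_pos, c1, c2, c3)
  if (jitter > 0) xyz <- xyz + matrix(stats::rnorm(12, 0, jitter), ncol = 3)
  molecule(data.frame(element = c("O", "C", "C", "C"),
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]),
           data.frame(i = c(1, 2, 2), j = c(2, 3, 4), order = c(2, 1, 1)),
           name = name)
}

#' Construct a toy receptor-ligand complex with a planted pose
#'
#' `binder` plants the ligand's carbonyl O on the hinge N-H axis at 2.9 A
#' (satisfying the hinge criterion by construction); `nonbinder` plants the
#' same probe deep in the pocket with its polar O at least 4 A from both
#' hinge backbone atoms; `clash` additionally drives one atom under the
#' hard-clash distance. The expected energy decomposition is computed with
#' the brute-force oracle.
#'
#' @param seed integer seed (controls pocket jitter and ligand placement).
#' @param kind one of `"binder"`, `"nonbinder"`, `"clash"`.
#' @param params a `ParameterSet`.
#' @return a `ToyComplex`: list with `receptor`, `ligand`, `planted_pose`,
#'   `expected` (oracle `EnergyBreakdown`), `kind`, `seed`.
#' @export
make_toy_complex <- function(seed = 1, kind = c("binder", "nonbinder", "clash"),
                             params = default_parameters()) {
  kind <- match.arg(kind)
  rec <- make_toy_receptor(seed, params = params)
  rxyz <- as.matrix(rec$atoms[, c("x", "y", "z")])
  Npos <- rxyz[rec$hinge$N, ]; Hpos <- rxyz[rec$hinge$H, ]
  Opos <- rxyz[rec$hinge$O, ]
  u_nh <- unit3(Hpos - Npos)
  lig <- with_seed(seed * 31 + 7, function() {
    if (kind == "binder") {
      o_at <- Npos + 2.9 * u_nh
      make_probe_ligand(o_at, unit3(-o_at), name = sprintf("binder_s%d", seed))
    } else if (kind == "nonbinder") {
      # polar O planted deep in the cavity interior, away from the amide
      o_at <- c(0.2, -0.6, 0.5)
      m <- make_probe_ligand(o_at, c(-0.3, 0.4, -0.7),
                             name = sprintf("nonbinder_s%d", seed))
      stopifnot(sqrt(sum((o_at - Npos)^2)) >= 4.0,
                sqrt(sum((o_at - Opos)^2)) >= 4.0)
      m
    } else {
      # overlap a shell atom
      target <- rxyz[6, ]
      make_probe_ligand(target + c(0.5, 0, 0), c(-1, 0, 0),
                        name = sprintf("clash_s%d", seed))
    }
  })
  lig <- gasteiger_charges(lig)
  lig <- assign_atom_types(lig, params)
  lig <- build_torsion_tree(lig)
  pose <- identity_pose(lig)
  expected <- brute_force_energy(rec, lig, pose, params)
  out <- list(receptor = rec, ligand = lig, planted_pose = pose,
              expected = expected, kind = kind, seed = seed)
  class(out) <- "ToyComplex"
  out
}

#' @export
print.ToyComplex <- function(x, ...) {
  cat(sprintf("ToyComplex (%s, seed %d): %d receptor atoms, %d ligand atoms, dG = %.4f\n",
              x$kind, x$seed, nrow(x$receptor$atoms), nrow(x$ligand$atoms),
              x$expected$total))
  invisible(x)
}

# zigzag heavy-atom alkane (hydrogens implicit)
#' @noRd
make_alkane <- function(n_c, name, jitter = 0.05) {
  xyz <- matrix(0, n_c, 3)
  for (i in seq_len(n_c)[-1]) {
    dir <- unit3(c(1, 0.45 * (-1)^i, 0.1 * sin(i)))
    xyz[i, ] <- xyz[i - 1, ] + 1.53 * dir
  }
  xyz <- xyz + matrix(stats::rnorm(3 * n_c, 0, jitter), ncol = 3)
  xyz <- sweep(xyz, 2, colMeans(xyz))
  bonds <- if (n_c > 1) data.frame(i = seq_len(n_c - 1), j = 2:n_c, order = 1L)
           else NULL
  molecule(data.frame(element = rep("C", n_c),
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]), bonds, name)
}

#' Generate a labeled synthetic screening library
#'
#' `n` small molecules: a fraction `frac_binders` are rigid polar probes
#' designed to form the hinge hydrogen bond when docked (each carries one
#' carbonyl acceptor), the rest are nonpolar hydrocarbons that cannot
#' satisfy the hinge criterion by construction. A few percent of the
#' nonbinders are oversized/greasy so they violate at least two
#' Rule-of-Five rules (drug-likeness failures). Deterministic per seed.
#'
#' @param seed integer seed.
#' @param n library size (>= 0).
#' @param frac_binders fraction of planted hinge binders, in `[0, 1]`.
#' @return list with `molecules` (list of `Molecule`) and `labels`
#'   (data.frame: id, binder, ro5_expected).
#' @export
make_library <- function(seed = 1, n = 200, frac_binders = 0.1) {
  stopifnot(n >= 0, frac_binders >= 0, frac_binders <= 1)
  n_bind <- round(n * frac_binders)
  n_fail <- if (n - n_bind >= 8) max(0L, round(n * 0.04)) else 0L
  with_seed(seed * 1009 + 3, function() {
    mols <- list(); labels <- list()
    for (k in seq_len(n)) {
      id <- sprintf("LIB%04d", k)
      if (k <= n_bind) {
        m <- make_probe_ligand(c(0, 0, 0), unit3(stats::rnorm(3)), name = id,
                               jitter = 0.04)
        lab <- data.frame(id = id, binder = TRUE, ro5_expected = TRUE)
      } else if (k <= n_bind + n_fail) {
        m <- make_alkane(42, id)   # MW and logP both far over the limits
        lab <- data.frame(id = id, binder = FALSE, ro5_expected = FALSE)
      } else {
        m <- make_alkane(3 + (k %% 5), id)
        lab <- data.frame(id = id, binder = FALSE, ro5_expected = TRUE)
      }
      mols[[k]] <- m
      labels[[k]] <- lab
    }
    list(molecules = mols, labels = do.call(rbind, labels))
  })
}

#' Emit a fixture set to a directory (PDB receptor, SDF ligands, labels TSV)
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed.
#' @param n_library library size.
#' @return the directory path, invisibly.
#' @export
write_fixture_set <- function(dir, seed = 1, n_library = 20) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tc <- make_toy_complex(seed, "binder")
  write_receptor_pdb(tc$receptor, file.path(dir, "toy_receptor_synthetic.pdb"))
  write_sdf(tc$ligand, file.path(dir, "toy_binder_synthetic.sdf"),
            energies = tc$expected$total)
  lib <- make_library(seed, n_library)
  write_sdf(lib$molecules, file.path(dir, "toy_library_synthetic.sdf"))
  utils::write.table(lib$labels, file.path(dir, "toy_library_labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
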