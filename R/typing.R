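# Atom typing: map each atom to a force-field type code in the active
# ParameterSet, flag hydrogen-bond roles, and attach solvation parameters.

#' @noRd
type_atoms_impl <- function(atoms, bonds, aromatic, params) {
  n <- nrow(atoms)
  el <- atoms$element
  nb <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds$i[k]; j <- bonds$j[k]
    nb[[i]] <- c(nb[[i]], j); nb[[j]] <- c(nb[[j]], i)
  }
  has_polar_parent <- function(i) {
    length(nb[[i]]) > 0 && any(el[nb[[i]]] %in% c("N", "O", "S"))
  }
  n_h <- vapply(seq_len(n), function(i) sum(el[nb[[i]]] == "H"), numeric(1))
  heavy_deg <- vapply(seq_len(n), function(i) sum(el[nb[[i]]] != "H"), numeric(1))

  code <- character(n)
  for (i in seq_len(n)) {
    code[i] <- switch(el[i],
      H  = if (has_polar_parent(i)) "HD" else "H",
      C  = if (aromatic[i]) "A" else "C",
      N  = if (n_h[i] > 0) {
             if (heavy_deg[i] <= 2 && !aromatic[i]) "NDA" else "ND"
           } else "N",
      O  = if (n_h[i] > 0) "ODA" else "OA",
      S  = if (n_h[i] > 0) "SH" else "SA",
      F  = "F", Cl = "CL", Br = "BR", I = "I", P = "P",
      stop("cannot type atom ", i, " (element ", el[i], ") in molecule")
    )
  }
  idx <- match(code, params$types$code)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    stop("atom ", bad, " typed '", code[bad], "' which is absent from the ParameterSet")
  }
  role <- ifelse(params$types$donor[idx] & params$types$acceptor[idx], "donor-acceptor",
          ifelse(params$types$donor[idx], "donor-heavy",
          ifelse(params$types$acceptor[idx], "acceptor",
          ifelse(code == "HD", "polar-hydrogen", "none"))))
  atoms$type_code <- code
  atoms$hbond_role <- role
  atoms$S <- params$types$S[idx]
  atoms$V <- params$types$V[idx]
  atoms$occmax <- params$types$occmax[idx]
  atoms
}

#' Assign force-field atom types, hydrogen-bond roles and solvation parameters
#'
#' Every atom is mapped to exactly one type code of the active
#' [default_parameters()] table from its element, aromaticity and bonded
#' hydrogens; donor/acceptor roles follow from the type (a hydroxyl oxygen is
#' both donor-heavy and acceptor; its hydrogen is a polar hydrogen), and the
#' per-type solvation triple (S, V, occmax) of the dehydration term is
#' attached.
#'
#' @param mol a `Molecule` with elements and bonds populated.
#' @param params a `ParameterSet`.
#' @return the molecule with `type_code`, `hbond_role`, `S`, `V`, `occmax` set.
#' @export
assign_atom_types <- function(mol, params = default_parameters()) {
  mol$atoms <- type_atoms_impl(mol$atoms, mol$bonds, aromatic_atoms(mol), params)
  mol
}

#' @noRd
is_donor_heavy <- function(role) role %in% c("donor-heavy", "donor-acceptor")

#' @noRd
is_acceptor <- function(role) role %in% c("acceptor", "donor-acceptor")
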