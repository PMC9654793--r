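#' Construct a ligand molecule
#'
#' The ligand-side data model: a data frame of atoms (element, Cartesian
#' coordinates in Angstrom, partial charge in e, force-field type code,
#' hydrogen-bond role and solvation parameters) plus a bond list with orders.
#' The torsion tree (root rigid fragment + rotatable-bond branches) is built
#' lazily by [build_torsion_tree()].
#'
#' @param atoms data.frame with at least `element`, `x`, `y`, `z`; optional
#'   `charge` (defaults 0) and `formal_charge` (defaults 0).
#' @param bonds data.frame with columns `i`, `j`, `order` (1, 2, 3; 4 is
#'   accepted as aromatic).
#' @param name stable identifier.
#' @return object of class `Molecule`.
#' @export
molecule <- function(atoms, bonds, name = "mol") {
  stopifnot(is.data.frame(atoms), all(c("element", "x", "y", "z") %in% names(atoms)))
  atoms$element <- normalize_element(atoms$element)
  if (is.null(atoms$charge)) atoms$charge <- 0
  if (is.null(atoms$formal_charge)) atoms$formal_charge <- 0
  for (col in c("type_code", "hbond_role")) if (is.null(atoms[[col]])) atoms[[col]] <- NA_character_
  for (col in c("S", "V", "occmax")) if (is.null(atoms[[col]])) atoms[[col]] <- NA_real_
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite coordinates in molecule '", name, "'")
  }
  if (is.null(bonds) || nrow(bonds) == 0) {
    bonds <- data.frame(i = integer(), j = integer(), order = integer())
  }
  stopifnot(all(c("i", "j") %in% names(bonds)))
  if (is.null(bonds$order)) bonds$order <- 1L
  rownames(atoms) <- NULL
  mol <- list(name = name, atoms = atoms, bonds = bonds,
              n_tor = NA_integer_, torsion_tree = NULL)
  class(mol) <- "Molecule"
  mol
}

#' @export
print.Molecule <- function(x, ...) {
  nh <- sum(x$atoms$element != "H")
  cat(sprintf("Molecule '%s': %d atoms (%d heavy), %d bonds, n_tor = %s\n",
              x$name, nrow(x$atoms), nh, nrow(x$bonds),
              ifelse(is.na(x$n_tor), "?", x$n_tor)))
  invisible(x)
}

#' Atom coordinates as an n x 3 matrix
#' @param mol a `Molecule` (or any object with an `atoms` data frame).
#' @export
coords <- function(mol) {
  as.matrix(mol$atoms[, c("x", "y", "z")])
}

#' @noRd
set_coords <- function(mol, xyz) {
  mol$atoms[, c("x", "y", "z")] <- xyz
  mol
}

#' @noRd
mol_graph <- function(mol) {
  igraph::graph_from_data_frame(
    data.frame(from = mol$bonds$i, to = mol$bonds$j),
    directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(mol$atoms))))
}

# adjacency list: neighbors[[i]] = integer vector of bonded atom indices
#' @noRd
neighbor_list <- function(mol) {
  n <- nrow(mol$atoms)
  nb <- vector("list", n)
  for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
    nb[[i]] <- c(nb[[i]], j)
    nb[[j]] <- c(nb[[j]], i)
  }
  nb
}

# bond-count separation matrix (graph distance; Inf if disconnected)
#' @noRd
bond_separation <- function(mol) {
  if (nrow(mol$bonds) == 0) {
    n <- nrow(mol$atoms)
    m <- matrix(Inf, n, n); diag(m) <- 0
    return(m)
  }
  igraph::distances(mol_graph(mol))
}

# logical vector over bonds: TRUE if the bond lies in a ring
#' @noRd
ring_bonds <- function(mol) {
  nb <- nrow(mol$bonds)
  if (nb == 0) return(logical(0))
  g <- mol_graph(mol)
  br <- igraph::bridges(g)
  in_ring <- rep(TRUE, nb)
  if (length(br) > 0) {
    ends <- igraph::ends(g, br)
    key <- paste(pmin(as.integer(ends[, 1]), as.integer(ends[, 2])),
                 pmax(as.integer(ends[, 1]), as.integer(ends[, 2])))
    bkey <- paste(pmin(mol$bonds$i, mol$bonds$j), pmax(mol$bonds$i, mol$bonds$j))
    in_ring[bkey %in% key] <- FALSE
  }
  in_ring
}

# Aromatic atom flags: explicit aromatic bond order 4, or membership in a
# fused 5/6-ring system of C/N/O/S atoms that carries conjugation (every ring
# atom participates in at least one double or aromatic bond within the ring
# system). Adequate for the drug-like chemistry this toolkit handles.
#' @noRd
aromatic_atoms <- function(mol) {
  n <- nrow(mol$atoms)
  flag <- rep(FALSE, n)
  if (nrow(mol$bonds) == 0) return(flag)
  rb <- ring_bonds(mol)
  if (!any(rb)) return(flag)
  arom_bond <- mol$bonds$order == 4 & rb
  flag[unique(c(mol$bonds$i[arom_bond], mol$bonds$j[arom_bond]))] <- TRUE
  # Kekulized rings: components of the ring-bond subgraph
  ring_edge <- mol$bonds[rb, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    data.frame(from = ring_edge$i, to = ring_edge$j), directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  comp <- igraph::components(g)
  keep <- which(comp$csize >= 5)
  for (cc in keep) {
    members <- which(comp$membership == cc)
    ok_elem <- all(mol$atoms$element[members] %in% c("C", "N", "O", "S"))
    if (!ok_elem) next
    conj <- vapply(members, function(a) {
      any((mol$bonds$i == a | mol$bonds$j == a) & mol$bonds$order %in% c(2L, 4L))
    }, logical(1))
    if (all(conj)) flag[members] <- TRUE
  }
  flag
}

# polar hydrogens: H bonded to N, O or S
#' @noRd
polar_h <- function(mol) {
  isH <- mol$atoms$element == "H"
  flag <- rep(FALSE, nrow(mol$atoms))
  for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
    if (isH[i] && mol$atoms$element[j] %in% c("N", "O", "S")) flag[i] <- TRUE
    if (isH[j] && mol$atoms$element[i] %in% c("N", "O", "S")) flag[j] <- TRUE
  }
  flag
}

#' Count rotatable bonds and build the torsion tree
#'
#' A bond is a heavy-atom rotor when it is a single, acyclic (bridge) bond
#' between two heavy atoms that each carry at least one further heavy
#' neighbor, and is not an amide C-N bond. Terminal methyl (and other
#' all-hydrogen-terminated) rotors are thereby excluded. Polar-hydrogen
#' rotors (hydroxyl, primary amine) are always sampled as torsions and are
#' counted in `n_tor` by default, since the entropy penalty models all
#' rotors frozen on binding.
#'
#' @param mol a `Molecule`.
#' @param count_polar_h include polar-H rotors in `n_tor` (default TRUE).
#' @return the molecule with `torsion_tree` and `n_tor` set.
#' @export
build_torsion_tree <- function(mol, count_polar_h = TRUE) {
  n <- nrow(mol$atoms)
  heavy <- mol$atoms$element != "H"
  nb <- neighbor_list(mol)
  rb <- ring_bonds(mol)
  is_amide <- function(i, j) {
    # C(=O)-N single bond, either orientation
    for (ord in list(c(i, j), c(j, i))) {
      a <- ord[1]; b <- ord[2]
      if (mol$atoms$element[a] == "C" && mol$atoms$element[b] == "N") {
        dbl_o <- any(vapply(seq_len(nrow(mol$bonds)), function(k) {
          bo <- mol$bonds[k, ]
          bo$order == 2 &&
            ((bo$i == a && mol$atoms$element[bo$j] == "O") ||
             (bo$j == a && mol$atoms$element[bo$i] == "O"))
        }, logical(1)))
        if (dbl_o) return(TRUE)
      }
    }
    FALSE
  }
  heavy_deg <- vapply(seq_len(n), function(i) sum(heavy[nb[[i]]]), numeric(1))
  kind <- character(0); blist <- list()
  for (k in seq_len(nrow(mol$bonds))) {
    if (mol$bonds$order[k] != 1 || rb[k]) next
    i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
    if (!heavy[i] || !heavy[j]) next
    if (heavy_deg[i] >= 2 && heavy_deg[j] >= 2) {
      if (is_amide(i, j)) next
      blist[[length(blist) + 1]] <- c(i, j); kind <- c(kind, "heavy")
    } else {
      # polar-H rotor: distal atom's other neighbors are all H, >=1 polar H
      for (ord in list(c(i, j), c(j, i))) {
        a <- ord[1]; b <- ord[2]   # b distal
        others <- setdiff(nb[[b]], a)
        if (length(others) > 0 && all(mol$atoms$element[others] == "H") &&
            mol$atoms$element[b] %in% c("N", "O", "S") && heavy_deg[a] >= 1) {
          blist[[length(blist) + 1]] <- c(a, b); kind <- c(kind, "polarH")
          break
        }
      }
    }
  }
  # rigid fragments: components after deleting rotor bonds
  keep <- rep(TRUE, nrow(mol$bonds))
  if (length(blist) > 0) {
    bkey <- paste(pmin(mol$bonds$i, mol$bonds$j), pmax(mol$bonds$i, mol$bonds$j))
    rkey <- vapply(blist, function(b) paste(min(b), max(b)), character(1))
    keep <- !(bkey %in% rkey)
  }
  gf <- igraph::graph_from_data_frame(
    data.frame(from = mol$bonds$i[keep], to = mol$bonds$j[keep]),
    directed = FALSE, vertices = data.frame(name = seq_len(max(n, 1))))
  comp <- igraph::components(gf)$membership
  frag_heavy <- tapply(heavy, comp, sum)
  root_frag <- as.integer(names(frag_heavy)[which.max(frag_heavy)])
  root_atoms <- which(comp == root_frag)
  # moved set per rotor: side of the bond not containing the root fragment
  g_all <- mol_graph(mol)
  branches <- lapply(seq_along(blist), function(bi) {
    b <- blist[[bi]]
    g_cut <- igraph::delete_edges(
      g_all, igraph::get_edge_ids(g_all, c(b[1], b[2])))
    cc <- igraph::components(g_cut)$membership
    side_j <- which(cc == cc[b[2]])
    if (any(root_atoms %in% side_j)) {
      # orient so axis points root -> moved
      b <- c(b[2], b[1])
      side_j <- which(cc == cc[b[2]])
    }
    list(bond = b, moved = setdiff(side_j, b[1]), kind = kind[bi])
  })
  # apply order: larger moved sets (closer to root) first
  if (length(branches) > 0) {
    branches <- branches[order(-vapply(branches, function(b) length(b$moved),
                                       numeric(1)))]
  }
  mol$torsion_tree <- list(root_atoms = root_atoms, branches = branches)
  mol$n_tor <- if (count_polar_h) length(branches) else
    sum(vapply(branches, function(b) b$kind == "heavy", logical(1)))
  mol
}

#' Number of rotatable bonds
#'
#' @inheritParams build_torsion_tree
#' @return integer rotor count (also stored on the molecule by
#'   [build_torsion_tree()]).
#' @export
count_rotatable_bonds <- function(mol, count_polar_h = TRUE) {
  build_torsion_tree(mol, count_polar_h)$n_tor
}
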