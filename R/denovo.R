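# Core-fixed de novo growth: enumerate substituents at marked attachment
# points of a docked scaffold, place them at ideal geometry, optimize only
# the substituent dihedrals while every core atom stays frozen at the
# docked coordinates, score with the five-term function, filter, rank.

#' Default substituent fragment library
#'
#' Small substituents in idealized local geometry: the attachment atom sits
#' at the origin with the bond-to-core along -x. `H` (the null substitution)
#' is always present.
#'
#' @return named list of fragments (`atoms`, `bonds`, `attach`,
#'   `bond_length` to an sp2/sp3 carbon core atom).
#' @export
default_fragment_library <- function() {
  tet <- 109.47 * pi / 180
  # three tetrahedral directions completing a bond that points along -x
  tdirs <- t(vapply(c(0, 120, 240) * pi / 180, function(phi) {
    c(-cos(tet), sin(tet) * cos(phi), sin(tet) * sin(phi))
  }, numeric(3)))
  frag <- function(name, el, xyz, bonds, bond_length) {
    list(name = name,
         atoms = data.frame(element = el, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]),
         bonds = bonds, attach = 1L, bond_length = bond_length)
  }
  ch3 <- frag("methyl", c("C", "H", "H", "H"),
              rbind(c(0, 0, 0), 1.09 * tdirs),
              data.frame(i = c(1, 1, 1), j = c(2, 3, 4), order = 1), 1.53)
  # ethyl: C2 along a tetrahedral direction, methyl completed on C2
  c2 <- 1.53 * tdirs[1, ]
  u2 <- unit3(tdirs[1, ])
  e2 <- any_perp(u2); f2 <- unit3(cross3(u2, e2))
  h2 <- t(vapply(c(60, 180, 300) * pi / 180, function(phi) {
    c2 + 1.09 * unit3(-u2 * cos(tet) + (e2 * cos(phi) + f2 * sin(phi)) * sin(tet))
  }, numeric(3)))
  ethyl <- frag("ethyl", c("C", "C", "H", "H", "H", "H", "H"),
                rbind(c(0, 0, 0), c2, 1.09 * tdirs[2, ], 1.09 * tdirs[3, ], h2),
                data.frame(i = c(1, 1, 1, 2, 2, 2), j = c(2, 3, 4, 5, 6, 7),
                           order = 1), 1.53)
  # methoxy: O attach, methyl beyond
  co <- 1.43 * tdirs[1, ]
  uo <- unit3(tdirs[1, ])
  eo <- any_perp(uo); fo <- unit3(cross3(uo, eo))
  ho <- t(vapply(c(60, 180, 300) * pi / 180, function(phi) {
    co + 1.09 * unit3(-uo * cos(tet) + (eo * cos(phi) + fo * sin(phi)) * sin(tet))
  }, numeric(3)))
  methoxy <- frag("methoxy", c("O", "C", "H", "H", "H"),
                  rbind(c(0, 0, 0), co, ho),
                  data.frame(i = c(1, 2, 2, 2), j = c(2, 3, 4, 5), order = 1), 1.36)
  # phenyl: ring in the xy plane, attached carbon at the origin
  ring <- t(vapply(0:5, function(k) {
    a <- pi + k * pi / 3   # C1 at angle pi about center (1.39, 0, 0)
    c(1.39 + 1.39 * cos(a), 1.39 * sin(a), 0)
  }, numeric(3)))
  hpos <- t(vapply(2:6, function(k) {
    ring[k, ] + 1.08 * unit3(ring[k, ] - c(1.39, 0, 0))
  }, numeric(3)))
  phenyl <- frag("phenyl", c(rep("C", 6), rep("H", 5)),
                 rbind(ring, hpos),
                 data.frame(i = c(1, 2, 3, 4, 5, 6, 2, 3, 4, 5, 6),
                            j = c(2, 3, 4, 5, 6, 1, 7, 8, 9, 10, 11),
                            order = c(2, 1, 2, 1, 2, 1, rep(1, 5))), 1.48)
  list(
    H = list(name = "H", atoms = NULL, bonds = NULL, attach = NA,
             bond_length = NA),
    methyl = ch3,
    ethyl = ethyl,
    methoxy = methoxy,
    chloro = frag("chloro", "Cl", matrix(0, 1, 3),
                  data.frame(i = integer(), j = integer(), order = integer()), 1.77),
    bromo = frag("bromo", "Br", matrix(0, 1, 3),
                 data.frame(i = integer(), j = integer(), order = integer()), 1.94),
    phenyl = phenyl
  )
}

#' Define a core template for derivative growth
#'
#' @param mol the scaffold `Molecule`.
#' @param attachment_points integer matrix/data.frame with columns `heavy`
#'   (heavy-atom index) and `hydrogen` (the terminal H replaced on
#'   substitution); distinct rows.
#' @param core_pose the scaffold's docked `Pose` (or NULL to grow in place).
#' @return object of class `CoreTemplate` whose `coords` are the realized
#'   docked coordinates.
#' @export
core_template <- function(mol, attachment_points, core_pose = NULL) {
  ap <- as.data.frame(attachment_points)
  names(ap) <- c("heavy", "hydrogen")
  if (anyDuplicated(ap$hydrogen)) stop("attachment points must be distinct")
  nb <- neighbor_list(mol)
  for (k in seq_len(nrow(ap))) {
    h <- ap$hydrogen[k]
    if (mol$atoms$element[h] != "H") stop("attachment atom ", h, " is not a hydrogen")
    if (!identical(as.integer(sort(nb[[h]])), as.integer(ap$heavy[k]))) {
      stop("attachment H ", h, " is not terminal on heavy atom ", ap$heavy[k])
    }
  }
  if (is.null(mol$torsion_tree)) mol <- build_torsion_tree(mol)
  xyz <- if (is.null(core_pose)) coords(mol) else realize_pose(mol, core_pose)
  out <- list(molecule = set_coords(mol, xyz), attachment_points = ap)
  class(out) <- "CoreTemplate"
  out
}

# build one derivative molecule at the docked core coordinates; fragment
# atom indices per site are recorded for the dihedral optimizer
#' @noRd
build_derivative <- function(core, assignment, frags) {
  mol <- core$molecule
  ap <- core$attachment_points
  drop_h <- integer(0)
  site_atoms <- vector("list", nrow(ap))
  atoms <- mol$atoms[, c("element", "x", "y", "z")]
  bonds <- mol$bonds
  for (s in seq_len(nrow(ap))) {
    fname <- assignment[s]
    if (fname == "H") next
    fr <- frags[[fname]]
    if (is.null(fr)) stop("unknown fragment: ", fname)
    drop_h <- c(drop_h, ap$hydrogen[s])
    P <- as.numeric(atoms[ap$heavy[s], c("x", "y", "z")])
    Hp <- as.numeric(mol$atoms[ap$hydrogen[s], c("x", "y", "z")])
    u <- unit3(Hp - P)
    # rotation mapping local +x onto u
    e1 <- c(1, 0, 0)
    axis <- cross3(e1, u)
    R <- if (sqrt(sum(axis^2)) < 1e-10) {
      if (sum(e1 * u) > 0) diag(3) else diag(c(1, -1, -1))
    } else {
      th <- acos(max(-1, min(1, sum(e1 * u))))
      K <- {
        a <- unit3(axis)
        matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3, byrow = TRUE)
      }
      diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
    }
    base <- nrow(atoms)
    fxyz <- as.matrix(fr$atoms[, c("x", "y", "z")]) %*% t(R)
    fxyz <- sweep(fxyz, 2, P + u * fr$bond_length, "+")
    atoms <- rbind(atoms, data.frame(element = fr$atoms$element,
                                     x = fxyz[, 1], y = fxyz[, 2], z = fxyz[, 3]))
    if (nrow(fr$bonds) > 0) {
      bonds <- rbind(bonds, data.frame(i = fr$bonds$i + base,
                                       j = fr$bonds$j + base,
                                       order = fr$bonds$order))
    }
    bonds <- rbind(bonds, data.frame(i = ap$heavy[s], j = base + fr$attach,
                                     order = 1L))
    site_atoms[[s]] <- list(idx = base + seq_len(nrow(fr$atoms)),
                            heavy = ap$heavy[s], axis_from = P)
  }
  # drop replaced hydrogens, remapping indices
  if (length(drop_h) > 0) {
    keep <- setdiff(seq_len(nrow(atoms)), drop_h)
    remap <- integer(nrow(atoms)); remap[keep] <- seq_along(keep)
    atoms <- atoms[keep, , drop = FALSE]
    bonds <- bonds[!(bonds$i %in% drop_h | bonds$j %in% drop_h), , drop = FALSE]
    bonds$i <- remap[bonds$i]; bonds$j <- remap[bonds$j]
    site_atoms <- lapply(site_atoms, function(sa) {
      if (is.null(sa)) return(NULL)
      sa$idx <- remap[sa$idx]; sa$heavy <- remap[sa$heavy]; sa
    })
    core_orig <- setdiff(seq_len(nrow(mol$atoms)), drop_h)
    core_idx <- remap[core_orig]
  } else {
    core_orig <- core_idx <- seq_len(nrow(mol$atoms))
  }
  d <- molecule(atoms, bonds,
                name = paste0(mol$name, "[", paste(assignment, collapse = ","), "]"))
  attr(d, "rgroups") <- assignment
  attr(d, "site_atoms") <- site_atoms
  attr(d, "core_atoms") <- core_idx   # indices in the derivative ...
  attr(d, "core_orig") <- core_orig   # ... of these original core atoms
  d
}

# canonical structure key for deduplication (element-colored canonical
# permutation + sorted bond list with orders)
#' @noRd
canonical_key <- function(mol) {
  n <- nrow(mol$atoms)
  if (nrow(mol$bonds) == 0) {
    return(paste(sort(mol$atoms$element), collapse = "."))
  }
  g <- mol_graph(mol)
  col <- as.integer(factor(mol$atoms$element,
                           levels = sort(unique(mol$atoms$element))))
  perm <- tryCatch(
    igraph::canonical_permutation(g, colors = col)$labeling,
    error = function(e) seq_len(n))
  inv <- integer(n); inv[perm] <- seq_len(n)
  el <- mol$atoms$element[order(perm)]
  eb <- cbind(pmin(perm[mol$bonds$i], perm[mol$bonds$j]),
              pmax(perm[mol$bonds$i], perm[mol$bonds$j]), mol$bonds$order)
  eb <- eb[order(eb[, 1], eb[, 2]), , drop = FALSE]
  paste(paste(el, collapse = "."),
        paste(apply(eb, 1, paste, collapse = "-"), collapse = "|"), sep = "//")
}

#' Enumerate derivatives of a core over a fragment library
#'
#' Full Cartesian product of fragments over the attachment points,
#' deduplicated by canonical structure; each derivative records its R-group
#' assignment. Spaces larger than `max_enum` are refused (grow a site subset
#' instead).
#'
#' @param core a [core_template()].
#' @param frags fragment library (default [default_fragment_library()]).
#' @param fragments_per_site optional character vector restricting the
#'   library per site (applied to all sites).
#' @param max_enum enumeration bound.
#' @return list of `Molecule`s with `rgroups` attributes; attribute
#'   `n_duplicates` counts removals.
#' @export
enumerate_derivatives <- function(core, frags = default_fragment_library(),
                                  fragments_per_site = names(frags),
                                  max_enum = 1e5) {
  stopifnot(nrow(core$attachment_points) >= 1)
  if (!"H" %in% fragments_per_site) {
    stop("the null substitution 'H' must be in the fragment library")
  }
  k <- nrow(core$attachment_points)
  total <- length(fragments_per_site)^k
  if (total > max_enum) {
    stop("combinatorial space (", total, ") exceeds max_enum (", max_enum, ")")
  }
  grid <- do.call(expand.grid, c(rep(list(fragments_per_site), k),
                                 stringsAsFactors = FALSE))
  out <- list(); seen <- new.env(hash = TRUE); ndup <- 0L
  for (r in seq_len(nrow(grid))) {
    assignment <- as.character(unlist(grid[r, ]))
    d <- tryCatch(build_derivative(core, assignment, frags),
                  error = function(e) NULL)
    if (is.null(d)) next
    key <- canonical_key(d)
    if (!is.null(seen[[key]])) { ndup <- ndup + 1L; next }
    seen[[key]] <- TRUE
    out[[length(out) + 1]] <- d
  }
  attr(out, "n_duplicates") <- ndup
  out
}

#' Score derivatives with the core frozen
#'
#' Each derivative keeps every core atom exactly at the docked coordinates;
#' only the substituent dihedral about each attachment bond is optimized
#' (coarse scan of `n_scan` angles per site, best kept, two passes). Scoring
#' uses the exact five-term function (or grid interpolation when `grids` is
#' given). Derivatives that cannot avoid a hard clash are scored and
#' flagged, not dropped.
#'
#' @param core a [core_template()].
#' @param derivatives from [enumerate_derivatives()].
#' @param rec prepared `Receptor`.
#' @param grids optional `GridMaps` for fast scoring.
#' @param params a `ParameterSet`.
#' @param n_scan dihedral scan resolution per site.
#' @return data.frame ranked by total energy ascending (id, R-groups,
#'   per-term energies, clash flag, rank), with the scored molecules in
#'   attribute `molecules`.
#' @export
grow_and_score <- function(core, derivatives, rec, grids = NULL,
                           params = default_parameters(), n_scan = 12) {
  score_fn <- function(m) {
    if (!is.null(grids)) grid_energy(grids, m, NULL, params)
    else binding_free_energy(rec, m, NULL, params)
  }
  rows <- list(); mols <- list()
  for (d in derivatives) {
    d <- gasteiger_charges(d)
    d <- assign_atom_types(d, params)
    d <- build_torsion_tree(d)
    sites <- Filter(Negate(is.null), attr(d, "site_atoms"))
    if (length(sites) > 0 && n_scan > 1) {
      angles <- seq(0, 360 * (n_scan - 1) / n_scan, length.out = n_scan)
      for (pass in 1:2) {
        for (sa in sites) {
          axis_pt <- as.numeric(d$atoms[sa$heavy, c("x", "y", "z")])
          # rotation axis: core heavy atom -> fragment attach atom
          att <- sa$idx[1]
          axis <- as.numeric(d$atoms[att, c("x", "y", "z")]) - axis_pt
          xyz0 <- coords(d)
          best <- list(e = Inf, xyz = xyz0)
          for (ang in angles) {
            xyz <- xyz0
            xyz[sa$idx, ] <- rotate_about_axis(xyz0[sa$idx, , drop = FALSE],
                                               axis_pt, axis, ang)
            e <- score_fn(set_coords(d, xyz))$total
            if (e < best$e) best <- list(e = e, xyz = xyz)
          }
          d <- set_coords(d, best$xyz)
        }
      }
    }
    sc <- score_fn(d)
    rg <- attr(d, "rgroups")
    row <- data.frame(id = d$name, total = sc$total, vdw = sc$vdw,
                      hbond = sc$hbond, elec = sc$elec, torsion = sc$torsion,
                      desolvation = sc$desolvation,
                      clash = isTRUE(sc$clash), stringsAsFactors = FALSE)
    for (s in seq_along(rg)) row[[paste0("R", s)]] <- rg[s]
    rows[[length(rows) + 1]] <- row
    mols[[d$name]] <- d
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$total, out$id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "molecules") <- mols
  out
}

#' Select the top-K druggable candidates
#'
#' Applies the Rule-of-Five filter to a ranked derivative table, then
#' truncates to `K` (ties already broken by energy then id upstream).
#'
#' @param ranked output of [grow_and_score()].
#' @param K number of candidates (> 0).
#' @param params a `ParameterSet`.
#' @return the filtered, truncated data.frame.
#' @export
select_candidates <- function(ranked, K, params = default_parameters()) {
  if (K <= 0) stop("K must be positive")
  mols <- attr(ranked, "molecules")
  ok <- vapply(ranked$id, function(id) rule_of_five(mols[[id]], params)$passed,
               logical(1))
  out <- ranked[ok, , drop = FALSE]
  out <- out[seq_len(min(K, nrow(out))), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "molecules") <- mols[out$id]
  out
}
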