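# Independent brute-force evaluation of the five-term score: a direct double
# loop over atom pairs with scalar arithmetic, no precomputed pair matrices,
# no grids and no vectorization. Kept deliberately separate from the scoring
# module so the two implementations cross-check each other.

#' Brute-force energy oracle
#'
#' Direct double-loop re-evaluation of the binding free energy from the term
#' definitions: receptor-ligand 12-6 / directional 12-10 / screened-Coulomb
#' pair sums, the rotor penalty, Gaussian-occupancy dehydration, and the
#' intra-ligand pair terms (>= 4 bonds apart or 1-4 across a rotor). Used as
#' the test oracle for [binding_free_energy()] and [grid_energy()].
#'
#' @param rec a prepared `Receptor`.
#' @param mol a typed, charged `Molecule`.
#' @param pose optional `Pose` (NULL scores the molecule in place).
#' @param params a `ParameterSet`.
#' @param cutoff pair cutoff, Angstrom; defaults to the parameter set's
#'   cutoff so the two implementations are comparable (use `Inf` for the
#'   no-cutoff variant).
#' @return an `EnergyBreakdown`.
#' @export
brute_force_energy <- function(rec, mol, pose = NULL,
                               params = default_parameters(),
                               cutoff = params$cutoff) {
  if (anyNA(mol$atoms$type_code)) mol <- assign_atom_types(mol, params)
  if (is.null(mol$torsion_tree)) mol <- build_torsion_tree(mol)
  lig <- if (is.null(pose)) coords(mol) else realize_pose(mol, pose)
  recxyz <- as.matrix(rec$atoms[, c("x", "y", "z")])
  nl <- nrow(lig); nr <- nrow(recxyz)
  tcodes <- params$types$code
  tr <- match(rec$atoms$type_code, tcodes)
  tl <- match(mol$atoms$type_code, tcodes)
  if (anyNA(tr) || anyNA(tl)) stop("untyped atom passed to brute_force_energy")
  don <- params$types$donor; acc <- params$types$acceptor
  ang <- params$angular
  diel <- params$dielectric

  # scalar helpers, written from the formulas; polar hydrogens have no 12-6
  # interaction with acceptors (their contact is the parent donor's H-bond)
  lj <- function(r, i, j) {
    if ((params$types$code[i] == "HD" && acc[j]) ||
        (params$types$code[j] == "HD" && acc[i])) return(0)
    rij <- (params$types$rii[i] + params$types$rii[j]) / 2
    e <- sqrt(params$types$eps[i] * params$types$eps[j])
    h <- params$smooth_width / 2
    r <- r + min(max(rij - r, -h), h)   # well smoothing
    (e * rij^12) / r^12 - (2 * e * rij^6) / r^6
  }
  hb1210 <- function(r) {
    h <- params$smooth_width / 2
    r <- r + min(max(params$hbond$r0 - r, -h), h)
    (5 * params$hbond$eps * params$hbond$r0^12) / r^12 -
      (6 * params$hbond$eps * params$hbond$r0^10) / r^10
  }
  epsr <- function(r) {
    B <- diel$eps_bulk - diel$A
    diel$A + B / (1 + diel$k * exp(-diel$lambda * B * r))
  }
  efac <- function(dev) if (dev >= 90) 0 else cos(dev * pi / 180)^ang$exponent
  vang <- function(u, v) {
    cv <- sum(u * v) / sqrt(sum(u * u) * sum(v * v))
    acos(max(-1, min(1, cv))) * 180 / pi
  }

  # bonded-neighbor bookkeeping (receptor + ligand, separately)
  rec_nb <- vector("list", nr)
  for (k in seq_len(nrow(rec$bonds))) {
    i <- rec$bonds$i[k]; j <- rec$bonds$j[k]
    rec_nb[[i]] <- c(rec_nb[[i]], j); rec_nb[[j]] <- c(rec_nb[[j]], i)
  }
  lig_nb <- vector("list", nl)
  for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
    lig_nb[[i]] <- c(lig_nb[[i]], j); lig_nb[[j]] <- c(lig_nb[[j]], i)
  }
  acc_axis <- function(pos, i, nbrs, elems, xyz) {
    heavy <- nbrs[elems[nbrs] != "H"]
    if (length(heavy) == 0) return(NULL)
    s <- c(0, 0, 0)
    for (h in heavy) s <- s + unit3(xyz[h, ] - pos)
    -unit3(s)
  }
  donor_E <- function(dpos, d_idx, hs, apos, xyz) {
    if (length(hs) == 0) return(1)
    best <- 0
    for (h in hs) {
      dev <- 180 - vang(dpos - xyz[h, ], apos - xyz[h, ])
      best <- max(best, efac(dev))
    }
    best
  }

  e_vdw <- 0; e_hb <- 0; e_el <- 0; e_sol <- 0
  clash <- FALSE
  # receptor-ligand pair sums
  for (i in seq_len(nr)) {
    for (j in seq_len(nl)) {
      r <- sqrt(sum((recxyz[i, ] - lig[j, ])^2))
      if (r <= 0 || r > cutoff) next
      if (r < params$hard_clash) clash <- TRUE
      ti <- tr[i]; tj <- tl[j]
      eligible <- (don[ti] && acc[tj]) || (acc[ti] && don[tj])
      if (eligible) {
        best <- 0
        if (don[ti] && acc[tj]) {
          hs <- rec_nb[[i]][rec$atoms$element[rec_nb[[i]]] == "H"]
          best <- max(best, donor_E(recxyz[i, ], i, hs, lig[j, ], recxyz))
        }
        if (acc[ti] && don[tj]) {
          ax <- acc_axis(recxyz[i, ], i, rec_nb[[i]], rec$atoms$element, recxyz)
          best <- max(best, if (is.null(ax)) 1 else
            efac(vang(ax, lig[j, ] - recxyz[i, ])))
        }
        e_hb <- e_hb + best * hb1210(r)
      } else {
        e_vdw <- e_vdw + lj(r, ti, tj)
      }
      e_el <- e_el + params$coulomb * rec$atoms$charge[i] * mol$atoms$charge[j] /
        (epsr(r) * r)
    }
  }
  # intra-ligand pairs
  sep <- bond_separation(mol)
  rot_keys <- vapply(mol$torsion_tree$branches,
                     function(b) paste(min(b$bond), max(b$bond)), character(1))
  g <- if (nrow(mol$bonds) > 0) mol_graph(mol) else NULL
  for (i in seq_len(max(nl - 1, 0))) {
    for (j in seq((i + 1), nl)) {
      include <- sep[i, j] >= 4 || !is.finite(sep[i, j])
      if (!include && sep[i, j] == 3 && length(rot_keys) > 0) {
        p <- as.integer(igraph::shortest_paths(g, i, j)$vpath[[1]])
        for (s in seq_len(length(p) - 1)) {
          if (paste(min(p[s], p[s + 1]), max(p[s], p[s + 1])) %in% rot_keys) {
            include <- TRUE; break
          }
        }
      }
      if (!include) next
      r <- sqrt(sum((lig[i, ] - lig[j, ])^2))
      if (r <= 0 || r > cutoff) next
      if (r < params$hard_clash) clash <- TRUE
      ti <- tl[i]; tj <- tl[j]
      eligible <- (don[ti] && acc[tj]) || (acc[ti] && don[tj])
      if (eligible) {
        best <- 0
        for (ord in list(c(i, j), c(j, i))) {
          d <- ord[1]; a <- ord[2]
          if (!(don[tl[d]] && acc[tl[a]])) next
          hs <- lig_nb[[d]][mol$atoms$element[lig_nb[[d]]] == "H"]
          best <- max(best, donor_E(lig[d, ], d, hs, lig[a, ], lig))
        }
        e_hb <- e_hb + best * hb1210(r)
      } else {
        e_vdw <- e_vdw + lj(r, ti, tj)
      }
      e_el <- e_el + params$coulomb * mol$atoms$charge[i] * mol$atoms$charge[j] /
        (epsr(r) * r)
    }
  }
  # dehydration
  if (isTRUE(params$use_solvation) && params$weights[["sol"]] > 0 && nl > 0) {
    for (i in seq_len(nl)) {
      occ <- 0
      for (j in seq_len(nr)) {
        r2 <- sum((lig[i, ] - recxyz[j, ])^2)
        if (r2 > 0 && sqrt(r2) <= cutoff) {
          occ <- occ + params$types$V[tr[j]] * exp(-r2 / (2 * params$sigma^2))
        }
      }
      for (j in seq_len(nl)) {
        if (j == i) next
        r2 <- sum((lig[i, ] - lig[j, ])^2)
        if (r2 > 0 && sqrt(r2) <= cutoff) {
          occ <- occ + params$types$V[tl[j]] * exp(-r2 / (2 * params$sigma^2))
        }
      }
      e_sol <- e_sol + params$types$S[tl[i]] * max(0, params$types$occmax[tl[i]] - occ)
    }
  }
  W <- params$weights
  energy_breakdown(vdw = W[["vdw"]] * e_vdw, hbond = W[["hbond"]] * e_hb,
                   elec = W[["elec"]] * e_el,
                   torsion = W[["tor"]] * mol$n_tor,
                   desolvation = W[["sol"]] * e_sol, clash = clash)
}
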