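# The modified protein-ligand binding free energy function: five weighted
# terms over receptor-ligand atom pairs --
#   W_vdw  * sum (A/r^12 - B/r^6)                 12-6 van der Waals
#   W_hb   * sum E(t) (C/r^12 - D/r^10)           directional hydrogen bond
#   W_elec * sum 332.06 q_i q_j / (eps(r) r)      sigmoidal dielectric
#   W_tor  * N_tor                                rotor entropy penalty
#   W_sol  * sum_i S_i max(0, Occmax_i - sum_j V_j exp(-r_ij^2 / 2 sigma^2))
# The last term is the solvent-contact dehydration energy: the Gaussian
# occupancy sum measures how buried each ligand atom is; its deficit from
# Occmax is the residual hydration, scaled by the atomic solvation energy
# density S_i.

#' Construct an energy decomposition
#' @noRd
energy_breakdown <- function(vdw = 0, hbond = 0, elec = 0, torsion = 0,
                             desolvation = 0, clash = FALSE) {
  out <- list(vdw = vdw, hbond = hbond, elec = elec, torsion = torsion,
              desolvation = desolvation,
              total = vdw + hbond + elec + torsion + desolvation,
              clash = clash)
  class(out) <- "EnergyBreakdown"
  out
}

#' @export
print.EnergyBreakdown <- function(x, ...) {
  cat(sprintf(
    "dG = %.4f kcal/mol (vdw %.4f | hbond %.4f | elec %.4f | tor %.4f | desolv %.4f)%s\n",
    x$total, x$vdw, x$hbond, x$elec, x$torsion, x$desolvation,
    if (isTRUE(x$clash)) " [CLASH]" else ""))
  invisible(x)
}

#' 12-6 van der Waals pair energy
#'
#' @param r interatomic distance, Angstrom (> 0).
#' @param pair numeric `c(A, B)` repulsion/dispersion coefficients.
#' @return energy in kcal/mol; minimum `-B^2/(4A)` at `r = (2A/B)^(1/6)`.
#' @export
vdw_term <- function(r, pair) {
  if (any(r <= 0)) stop("vdw_term: r must be positive")
  pair[[1]] / r^12 - pair[[2]] / r^6
}

#' Directional 12-10 hydrogen-bond pair energy
#'
#' `E(t) * (C/r^12 - D/r^10)` with the angular weight
#' `E(t) = cos^n(t - t_ideal)` (clamped to 0 beyond 90 degrees off ideal):
#' unity at the ideal donor-H...acceptor alignment and monotonically
#' decreasing away from it.
#'
#' @param r donor-acceptor heavy-atom distance, Angstrom (> 0).
#' @param t alignment angle, degrees in `[0, 180]` (ideal = `angular$ideal_deg`).
#' @param pair numeric `c(C, D)`.
#' @param angular list with `ideal_deg` and `exponent`.
#' @return energy in kcal/mol.
#' @export
hbond_term <- function(r, t, pair, angular = default_parameters()$angular) {
  if (any(r <= 0)) stop("hbond_term: r must be positive")
  stopifnot(all(t >= 0 & t <= 180))
  dev <- abs(t - angular$ideal_deg)
  E <- ifelse(dev >= 90, 0, cos(dev * pi / 180)^angular$exponent)
  E * (pair[[1]] / r^12 - pair[[2]] / r^10)
}

#' Screened Coulomb pair energy with sigmoidal distance-dependent dielectric
#'
#' @param r distance, Angstrom (> 0).
#' @param q_i,q_j partial charges, e.
#' @param dielectric sigmoidal dielectric constants (see
#'   [sigmoidal_dielectric()]).
#' @param coulomb electrostatic constant, kcal A / (mol e^2).
#' @return energy in kcal/mol.
#' @export
elec_term <- function(r, q_i, q_j, dielectric = default_parameters()$dielectric,
                      coulomb = 332.06) {
  if (any(r <= 0)) stop("elec_term: r must be positive")
  coulomb * q_i * q_j / (sigmoidal_dielectric(r, dielectric) * r)
}

#' Rotor entropy penalty
#'
#' Pose-independent torsional free energy cost `W_tor * N_tor`.
#'
#' @param n_tor rotatable-bond count (>= 0).
#' @param W_tor torsional weight, kcal/mol per rotor.
#' @return energy in kcal/mol.
#' @export
torsion_penalty <- function(n_tor, W_tor) {
  stopifnot(n_tor >= 0)
  W_tor * n_tor
}

#' Solvent-contact dehydration energy
#'
#' For each ligand atom `i`, the Gaussian-weighted volumes of all neighbor
#' atoms (receptor plus the ligand's other atoms) are summed into an
#' occupancy; the deficit from the atom's maximum occupancy, clamped at
#' zero, is scaled by its atomic solvation energy density `S_i`.
#'
#' @param lig_atoms data.frame of ligand atoms with `x`,`y`,`z`,`S`,`occmax`.
#' @param neighbor_atoms data.frame of neighbor atoms with `x`,`y`,`z`,`V`
#'   (exclude the atom itself).
#' @param sigma Gaussian width, Angstrom.
#' @param W_sol desolvation weight.
#' @param cutoff neighbor distance cutoff, Angstrom (Inf for none).
#' @return energy in kcal/mol.
#' @export
desolvation_term <- function(lig_atoms, neighbor_atoms, sigma, W_sol,
                             cutoff = Inf) {
  if (anyNA(lig_atoms$S) || anyNA(lig_atoms$occmax)) {
    stop("missing solvation parameters for ligand atom type(s): ",
         paste(unique(lig_atoms$type_code[is.na(lig_atoms$S)]), collapse = ", "))
  }
  lp <- as.matrix(lig_atoms[, c("x", "y", "z")])
  if (nrow(neighbor_atoms) == 0) {
    return(W_sol * sum(lig_atoms$S * pmax(0, lig_atoms$occmax)))
  }
  np <- as.matrix(neighbor_atoms[, c("x", "y", "z")])
  d2 <- outer(lp[, 1], np[, 1], "-")^2 + outer(lp[, 2], np[, 2], "-")^2 +
    outer(lp[, 3], np[, 3], "-")^2
  g <- exp(-d2 / (2 * sigma^2))
  if (is.finite(cutoff)) g[d2 > cutoff^2] <- 0
  occ <- as.numeric(g %*% neighbor_atoms$V)
  W_sol * sum(lig_atoms$S * pmax(0, lig_atoms$occmax - occ))
}

# well-smoothed evaluation distance: clamp r to within half the smoothing
# width of the pair minimum before applying the steep radial profile
#' @noRd
smooth_r <- function(r, rmin, width) {
  h <- width / 2
  r + pmin(pmax(rmin - r, -h), h)
}

# angular weight from a deviation angle (deg) off perfect alignment
#' @noRd
E_from_dev <- function(dev, angular) {
  ifelse(dev >= 90, 0, cos(pmin(dev, 90) * pi / 180)^angular$exponent)
}

#' @noRd
angle_deg <- function(u, v) {
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(max(-1, min(1, cosang))) * 180 / pi
}

# E(t) for one receptor-atom/ligand-position pair, receptor-side geometry
# only (donor N-H axis or acceptor lone-pair axis); returns 0 if the pair
# has no eligible orientation
#' @noRd
receptor_side_E <- function(i_rec, lig_pos, lig_is_acc, lig_is_don,
                            rxyz, rec_roles, polar, angular) {
  best <- -1
  role <- rec_roles[i_rec]
  if (is_donor_heavy(role) && lig_is_acc) {
    hs <- polar$don_h[[i_rec]]
    if (length(hs) > 0) {
      for (h in hs) {
        # D-H...A angle at the hydrogen; ideal 180
        dev <- 180 - angle_deg(rxyz[i_rec, ] - rxyz[h, ], lig_pos - rxyz[h, ])
        best <- max(best, E_from_dev(dev, angular))
      }
    } else best <- max(best, 1)
  }
  if (is_acceptor(role) && lig_is_don) {
    ax <- polar$acc_dir[i_rec, ]
    if (anyNA(ax)) best <- max(best, 1) else {
      dev <- angle_deg(ax, lig_pos - rxyz[i_rec, ])
      best <- max(best, E_from_dev(dev, angular))
    }
  }
  max(best, 0)
}

# intra-ligand interaction mask: pairs >= 4 bonds apart, or 1-4 pairs whose
# path crosses a rotatable bond
#' @noRd
intra_pair_list <- function(mol) {
  n <- nrow(mol$atoms)
  if (n < 2) return(matrix(integer(0), 0, 2))
  sep <- bond_separation(mol)
  pairs <- which(upper.tri(sep) & (sep >= 4 | !is.finite(sep)), arr.ind = TRUE)
  sep3 <- which(upper.tri(sep) & sep == 3, arr.ind = TRUE)
  if (nrow(sep3) > 0 && !is.null(mol$torsion_tree) &&
      length(mol$torsion_tree$branches) > 0) {
    g <- mol_graph(mol)
    rkey <- vapply(mol$torsion_tree$branches, function(b)
      paste(min(b$bond), max(b$bond)), character(1))
    keep <- vapply(seq_len(nrow(sep3)), function(k) {
      p <- as.integer(igraph::shortest_paths(g, sep3[k, 1], sep3[k, 2])$vpath[[1]])
      pk <- paste(pmin(p[-length(p)], p[-1]), pmax(p[-length(p)], p[-1]))
      any(pk %in% rkey)
    }, logical(1))
    pairs <- rbind(pairs, sep3[keep, , drop = FALSE])
  }
  pairs
}

# ligand-side polar geometry at given coordinates (used for intra terms)
#' @noRd
ligand_polar_geometry <- function(mol, xyz) {
  n <- nrow(mol$atoms)
  nb <- neighbor_list(mol)
  don_h <- vector("list", n)
  acc_dir <- matrix(NA_real_, n, 3)
  el <- mol$atoms$element
  for (i in seq_len(n)) {
    role <- mol$atoms$hbond_role[i]
    if (is.na(role)) next
    if (is_donor_heavy(role)) {
      hs <- nb[[i]][el[nb[[i]]] == "H"]
      if (length(hs) > 0) don_h[[i]] <- hs
    }
    if (is_acceptor(role)) {
      heavy <- nb[[i]][el[nb[[i]]] != "H"]
      if (length(heavy) > 0) {
        s <- colSums(matrix(t(apply(xyz[heavy, , drop = FALSE], 1,
                                    function(p) unit3(p - xyz[i, ]))), ncol = 3))
        acc_dir[i, ] <- -unit3(s)
      }
    }
  }
  list(don_h = don_h, acc_dir = acc_dir)
}

# hydrogen-bond E factor for an intra-ligand pair (both sides' geometry
# known); best over the two possible donor->acceptor orientations
#' @noRd
intra_E <- function(i, j, xyz, roles, polar, angular) {
  best <- -1
  for (ord in list(c(i, j), c(j, i))) {
    d <- ord[1]; a <- ord[2]
    if (!(is_donor_heavy(roles[d]) && is_acceptor(roles[a]))) next
    hs <- polar$don_h[[d]]
    if (length(hs) > 0) {
      for (h in hs) {
        dev <- 180 - angle_deg(xyz[d, ] - xyz[h, ], xyz[a, ] - xyz[h, ])
        best <- max(best, E_from_dev(dev, angular))
      }
    } else best <- max(best, 1)
  }
  max(best, 0)
}

#' Binding free energy of a ligand pose
#'
#' Evaluates the five-term score over all receptor-ligand atom pairs within
#' the nonbonded cutoff and returns the weighted per-term decomposition.
#' Pairs eligible for the hydrogen-bond term (donor-heavy vs acceptor, by
#' type) are excluded from the van der Waals sum. Intra-ligand pair terms
#' are evaluated for atom pairs at least 4 bonds apart or 1-4 across a
#' rotatable bond; the desolvation occupancy of every ligand atom includes
#' both receptor atoms and the ligand's own other atoms. A steric contact
#' below the hard-clash distance is flagged (`$clash`), not rejected.
#'
#' @param rec a prepared `Receptor` (typed and charged).
#' @param mol a typed, charged `Molecule` (torsion tree built on demand).
#' @param pose optional `Pose`; when NULL the molecule's own coordinates are
#'   scored in place.
#' @param params a `ParameterSet`.
#' @return an `EnergyBreakdown` (components in kcal/mol, already
#'   weight-multiplied; `total` is their sum).
#' @export
binding_free_energy <- function(rec, mol, pose = NULL,
                                params = default_parameters()) {
  if (anyNA(mol$atoms$type_code)) mol <- assign_atom_types(mol, params)
  if (is.null(mol$torsion_tree)) mol <- build_torsion_tree(mol)
  lxyz <- if (is.null(pose)) coords(mol) else realize_pose(mol, pose)
  rxyz <- as.matrix(rec$atoms[, c("x", "y", "z")])
  W <- params$weights
  ti_r <- type_index(params, rec$atoms$type_code)
  ti_l <- type_index(params, mol$atoms$type_code)
  polar <- if (!is.null(rec$polar)) rec$polar else receptor_polar_geometry(rec)

  nl <- nrow(lxyz); nr <- nrow(rxyz)
  # per-dimension differences (not the |x|^2+|y|^2-2xy trick): keeps the
  # steep r^-12 walls in bitwise agreement with the scalar oracle
  D2 <- outer(rxyz[, 1], lxyz[, 1], "-")^2 + outer(rxyz[, 2], lxyz[, 2], "-")^2 +
    outer(rxyz[, 3], lxyz[, 3], "-")^2
  D <- sqrt(D2)
  within <- D <= params$cutoff & D > 0
  clash <- any(D < params$hard_clash)

  elig <- params$hb_elig[ti_r, ti_l, drop = FALSE]

  # van der Waals (non-H-bond pairs)
  mask_v <- within & !elig
  e_vdw <- 0
  if (any(mask_v)) {
    A <- params$pairA[ti_r, ti_l, drop = FALSE]
    B <- params$pairB[ti_r, ti_l, drop = FALSE]
    Rm <- params$pairRmin[ti_r, ti_l, drop = FALSE]
    rv <- smooth_r(D[mask_v], Rm[mask_v], params$smooth_width)
    e_vdw <- sum((A[mask_v] / rv^12) - (B[mask_v] / rv^6))
  }

  # hydrogen bond (directional, receptor-side geometry)
  e_hb <- 0
  hb_pairs <- which(within & elig, arr.ind = TRUE)
  if (nrow(hb_pairs) > 0) {
    Cm <- params$hbC[ti_r, ti_l, drop = FALSE]
    Dm <- params$hbD[ti_r, ti_l, drop = FALSE]
    lig_acc <- is_acceptor(mol$atoms$hbond_role)
    lig_don <- is_donor_heavy(mol$atoms$hbond_role)
    for (k in seq_len(nrow(hb_pairs))) {
      i <- hb_pairs[k, 1]; j <- hb_pairs[k, 2]
      E <- receptor_side_E(i, lxyz[j, ], lig_acc[j], lig_don[j],
                           rxyz, rec$atoms$hbond_role, polar, params$angular)
      r <- smooth_r(D[i, j], params$hbond$r0, params$smooth_width)
      e_hb <- e_hb + E * (Cm[i, j] / r^12 - Dm[i, j] / r^10)
    }
  }

  # electrostatics (all pairs within cutoff)
  e_el <- 0
  if (any(within)) {
    qq <- outer(rec$atoms$charge, mol$atoms$charge)
    e_el <- sum(params$coulomb * qq[within] /
                (sigmoidal_dielectric(D[within], params$dielectric) * D[within]))
  }

  # intra-ligand pair terms
  ipairs <- intra_pair_list(mol)
  if (nrow(ipairs) > 0) {
    lp <- ligand_polar_geometry(mol, lxyz)
    ligA <- params$pairA[ti_l, ti_l, drop = FALSE]
    ligB <- params$pairB[ti_l, ti_l, drop = FALSE]
    ligC <- params$hbC[ti_l, ti_l, drop = FALSE]
    ligDm <- params$hbD[ti_l, ti_l, drop = FALSE]
    lelig <- params$hb_elig[ti_l, ti_l, drop = FALSE]
    q <- mol$atoms$charge
    for (k in seq_len(nrow(ipairs))) {
      i <- ipairs[k, 1]; j <- ipairs[k, 2]
      r <- sqrt(sum((lxyz[i, ] - lxyz[j, ])^2))
      if (r > params$cutoff || r <= 0) next
      if (r < params$hard_clash) clash <- TRUE
      if (lelig[i, j]) {
        E <- intra_E(i, j, lxyz, mol$atoms$hbond_role, lp, params$angular)
        rs <- smooth_r(r, params$hbond$r0, params$smooth_width)
        e_hb <- e_hb + E * (ligC[i, j] / rs^12 - ligDm[i, j] / rs^10)
      } else {
        rs <- smooth_r(r, params$pairRmin[ti_l[i], ti_l[j]], params$smooth_width)
        e_vdw <- e_vdw + ligA[i, j] / rs^12 - ligB[i, j] / rs^6
      }
      e_el <- e_el + params$coulomb * q[i] * q[j] /
        (sigmoidal_dielectric(r, params$dielectric) * r)
    }
  }

  # dehydration: occupancy over receptor atoms + the ligand's other atoms
  e_sol <- 0
  if (isTRUE(params$use_solvation) && W["sol"] > 0) {
    lig_df <- data.frame(x = lxyz[, 1], y = lxyz[, 2], z = lxyz[, 3],
                         S = mol$atoms$S, occmax = mol$atoms$occmax,
                         type_code = mol$atoms$type_code)
    if (anyNA(rec$atoms$V)) stop("receptor atoms missing solvation parameters; run type_receptor()")
    # receptor occupancy
    g_rec <- exp(-D2 / (2 * params$sigma^2))
    g_rec[!within] <- 0
    occ <- as.numeric(t(g_rec) %*% rec$atoms$V)
    # ligand self occupancy (all other atoms, cutoff applied)
    if (nl > 1) {
      L2 <- outer(lxyz[, 1], lxyz[, 1], "-")^2 + outer(lxyz[, 2], lxyz[, 2], "-")^2 +
        outer(lxyz[, 3], lxyz[, 3], "-")^2
      gl <- exp(-L2 / (2 * params$sigma^2))
      diag(gl) <- 0
      gl[L2 > params$cutoff^2] <- 0
      occ <- occ + as.numeric(gl %*% mol$atoms$V)
    }
    if (anyNA(lig_df$S)) {
      stop("missing solvation parameters for ligand type(s): ",
           paste(unique(lig_df$type_code[is.na(lig_df$S)]), collapse = ", "))
    }
    e_sol <- sum(lig_df$S * pmax(0, lig_df$occmax - occ))
  }

  energy_breakdown(vdw = W[["vdw"]] * e_vdw,
                   hbond = W[["hbond"]] * e_hb,
                   elec = W[["elec"]] * e_el,
                   torsion = torsion_penalty(mol$n_tor, W[["tor"]]),
                   desolvation = W[["sol"]] * e_sol,
                   clash = clash)
}
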