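# Precomputed affinity maps over a search box: per-ligand-atom-type 12-6 and
# directional 12-10 probe sums, an electrostatic potential map per unit
# charge, and a Gaussian-weighted receptor occupancy map for the
# dehydration term. Because H-bond directionality is defined from the
# receptor atom's local geometry, it is baked into the maps exactly.

#' Define a grid box
#'
#' @param center box center, Angstrom (length-3).
#' @param extent edge lengths, Angstrom (length-3 or scalar).
#' @param spacing node spacing, Angstrom.
#' @return list with `origin`, `dims` (node counts), `spacing`.
#' @export
grid_box <- function(center, extent, spacing = 0.375) {
  stopifnot(spacing > 0, all(extent > 0))
  extent <- rep(extent, length.out = 3)
  dims <- pmax(2L, as.integer(ceiling(extent / spacing)) + 1L)
  origin <- center - (dims - 1) * spacing / 2
  list(origin = origin, dims = dims, spacing = spacing)
}

#' Box covering the whole receptor (blind, whole-domain search)
#' @param rec a `Receptor`.
#' @param pad margin beyond the receptor extent, Angstrom.
#' @param spacing node spacing, Angstrom.
#' @export
whole_domain_box <- function(rec, pad = 4, spacing = 0.375) {
  xyz <- as.matrix(rec$atoms[, c("x", "y", "z")])
  lo <- apply(xyz, 2, min) - pad
  hi <- apply(xyz, 2, max) + pad
  grid_box((lo + hi) / 2, hi - lo, spacing)
}

#' Precompute grid maps for a receptor
#'
#' At each grid node the per-type probe pair-energy sums (12-6 for plain
#' pairs, directional 12-10 for donor/acceptor pairs), the electrostatic
#' potential per unit probe charge, and the Gaussian-weighted receptor
#' volume occupancy are accumulated over all receptor atoms within the
#' nonbonded cutoff. Maps store unweighted sums; term weights are applied at
#' evaluation time.
#'
#' @param rec a prepared `Receptor` (typed + charged).
#' @param box from [grid_box()] / [whole_domain_box()].
#' @param params a `ParameterSet`.
#' @param types ligand atom types to build affinity maps for (default: all
#'   types in the parameter set).
#' @return object of class `GridMaps`.
#' @export
build_grids <- function(rec, box, params = default_parameters(),
                        types = params$types$code) {
  stopifnot(all(box$dims >= 2), box$spacing > 0)
  dims <- box$dims
  nn <- prod(dims)
  ax <- lapply(1:3, function(k) box$origin[k] + (seq_len(dims[k]) - 1) * box$spacing)
  nodes <- cbind(rep(ax[[1]], times = dims[2] * dims[3]),
                 rep(rep(ax[[2]], each = dims[1]), times = dims[3]),
                 rep(ax[[3]], each = dims[1] * dims[2]))
  rxyz <- as.matrix(rec$atoms[, c("x", "y", "z")])
  inside <- rxyz[, 1] >= box$origin[1] & rxyz[, 1] <= max(ax[[1]]) &
    rxyz[, 2] >= box$origin[2] & rxyz[, 2] <= max(ax[[2]]) &
    rxyz[, 3] >= box$origin[3] & rxyz[, 3] <= max(ax[[3]])
  if (!any(inside)) warning("grid box excludes every receptor atom")
  ti_r <- type_index(params, rec$atoms$type_code)
  ti_t <- type_index(params, types)
  don <- params$types$donor; acc <- params$types$acceptor
  polar <- if (!is.null(rec$polar)) rec$polar else receptor_polar_geometry(rec)

  vdw_maps <- stats::setNames(lapply(types, function(t) numeric(nn)), types)
  hb_maps <- stats::setNames(lapply(types, function(t) numeric(nn)), types)
  elec_map <- numeric(nn)
  occ_map <- numeric(nn)

  for (i in seq_len(nrow(rxyz))) {
    d2 <- (nodes[, 1] - rxyz[i, 1])^2 + (nodes[, 2] - rxyz[i, 2])^2 +
      (nodes[, 3] - rxyz[i, 3])^2
    w <- d2 <= params$cutoff^2 & d2 > 0
    if (!any(w)) next
    r <- sqrt(d2[w])
    qi <- rec$atoms$charge[i]
    elec_map[w] <- elec_map[w] + params$coulomb * qi /
      (sigmoidal_dielectric(r, params$dielectric) * r)
    occ_map[w] <- occ_map[w] + params$types$V[ti_r[i]] *
      exp(-d2[w] / (2 * params$sigma^2))
    # directional E factors, shared across probe types
    E_don <- NULL; E_acc <- NULL
    if (is_donor_heavy(rec$atoms$hbond_role[i])) {
      hs <- polar$don_h[[i]]
      if (length(hs) == 0) E_don <- rep(1, sum(w)) else {
        E_don <- rep(0, sum(w))
        for (h in hs) {
          v1 <- rxyz[i, ] - rxyz[h, ]
          v2 <- sweep(nodes[w, , drop = FALSE], 2, rxyz[h, ])
          cosang <- (v2 %*% v1) / (sqrt(sum(v1^2)) * sqrt(rowSums(v2^2)))
          dev <- 180 - acos(pmax(-1, pmin(1, cosang))) * 180 / pi
          E_don <- pmax(E_don, E_from_dev(dev, params$angular))
        }
      }
    }
    if (is_acceptor(rec$atoms$hbond_role[i])) {
      axd <- polar$acc_dir[i, ]
      if (anyNA(axd)) E_acc <- rep(1, sum(w)) else {
        v2 <- sweep(nodes[w, , drop = FALSE], 2, rxyz[i, ])
        cosang <- (v2 %*% axd) / sqrt(rowSums(v2^2))
        dev <- acos(pmax(-1, pmin(1, cosang))) * 180 / pi
        E_acc <- E_from_dev(dev, params$angular)
      }
    }
    for (k in seq_along(types)) {
      tt <- ti_t[k]
      eligible <- (don[ti_r[i]] && acc[tt]) || (acc[ti_r[i]] && don[tt])
      if (eligible) {
        E <- rep(0, sum(w))
        if (don[ti_r[i]] && acc[tt] && !is.null(E_don)) E <- pmax(E, E_don)
        if (acc[ti_r[i]] && don[tt] && !is.null(E_acc)) E <- pmax(E, E_acc)
        rs <- smooth_r(r, params$hbond$r0, params$smooth_width)
        hb_maps[[k]][w] <- hb_maps[[k]][w] +
          E * (params$hbC[ti_r[i], tt] / rs^12 - params$hbD[ti_r[i], tt] / rs^10)
      } else {
        rs <- smooth_r(r, params$pairRmin[ti_r[i], tt], params$smooth_width)
        vdw_maps[[k]][w] <- vdw_maps[[k]][w] +
          params$pairA[ti_r[i], tt] / rs^12 - params$pairB[ti_r[i], tt] / rs^6
      }
    }
  }
  out <- list(origin = box$origin, spacing = box$spacing, dims = dims,
              types = types,
              vdw = lapply(vdw_maps, array, dim = dims),
              hb = lapply(hb_maps, array, dim = dims),
              elec = array(elec_map, dim = dims),
              occ = array(occ_map, dim = dims))
  class(out) <- "GridMaps"
  out
}

#' @export
print.GridMaps <- function(x, ...) {
  cat(sprintf("GridMaps: %d x %d x %d nodes @ %.3f A, %d affinity type(s)\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing, length(x$types)))
  invisible(x)
}

# shared trilinear stencil for a set of points: flat corner indices (n x 8)
# and weights (n x 8); points must be inside the box
#' @noRd
trilinear_prep <- function(origin, spacing, dims, pts) {
  n <- nrow(pts)
  t <- sweep(pts, 2, origin) / spacing
  i0 <- pmin(pmax(floor(t), 0), matrix(rep(dims - 2, each = n), ncol = 3))
  f <- t - i0
  d1 <- dims[1]; d12 <- dims[1] * dims[2]
  base <- 1 + i0[, 1] + i0[, 2] * d1 + i0[, 3] * d12
  offs <- c(0, 1, d1, d1 + 1, d12, d12 + 1, d12 + d1, d12 + d1 + 1)
  idx <- outer(base, offs, "+")
  fx <- f[, 1]; fy <- f[, 2]; fz <- f[, 3]
  gx <- 1 - fx; gy <- 1 - fy; gz <- 1 - fz
  w <- cbind(gx * gy * gz, fx * gy * gz, gx * fy * gz, fx * fy * gz,
             gx * gy * fz, fx * gy * fz, gx * fy * fz, fx * fy * fz)
  list(idx = idx, w = w, n = n)
}

# interpolate one map at all stencil points (or a row subset)
#' @noRd
trilinear_eval <- function(arr, pr, rows = NULL) {
  if (is.null(rows)) {
    rowSums(matrix(arr[pr$idx], nrow = pr$n) * pr$w)
  } else {
    idx <- pr$idx[rows, , drop = FALSE]
    rowSums(matrix(arr[idx], nrow = length(rows)) * pr$w[rows, , drop = FALSE])
  }
}

# convenience wrapper: interpolate one array at points
#' @noRd
trilinear <- function(arr, origin, spacing, dims, pts) {
  trilinear_eval(arr, trilinear_prep(origin, spacing, dims, pts))
}

#' @noRd
inside_box <- function(grids, pts) {
  hi <- grids$origin + (grids$dims - 1) * grids$spacing
  all(pts[, 1] >= grids$origin[1] & pts[, 1] <= hi[1] &
      pts[, 2] >= grids$origin[2] & pts[, 2] <= hi[2] &
      pts[, 3] >= grids$origin[3] & pts[, 3] <= hi[3])
}

# per-molecule evaluation cache for the fast grid path: type groups,
# charges, solvation vectors, and the precomputed intra-ligand pair spec
# (indices, eligibility, pair coefficients) so per-pose evaluation does no
# graph work
#' @noRd
grid_ligand_cache <- function(mol, params) {
  if (anyNA(mol$atoms$type_code)) mol <- assign_atom_types(mol, params)
  if (is.null(mol$torsion_tree)) mol <- build_torsion_tree(mol)
  ti <- type_index(params, mol$atoms$type_code)
  ip <- intra_pair_list(mol)
  ispec <- NULL
  if (nrow(ip) > 0) {
    i <- ip[, 1]; j <- ip[, 2]
    lin <- cbind(ti[i], ti[j])
    ispec <- list(i = i, j = j,
                  elig = params$hb_elig[lin],
                  A = params$pairA[lin], B = params$pairB[lin],
                  Rmin = params$pairRmin[lin],
                  C = params$hbC[lin], D = params$hbD[lin],
                  qq = params$coulomb * mol$atoms$charge[i] * mol$atoms$charge[j])
  }
  list(mol = mol,
       by_type = split(seq_len(nrow(mol$atoms)), mol$atoms$type_code),
       charge = mol$atoms$charge,
       S = mol$atoms$S, occmax = mol$atoms$occmax, V = mol$atoms$V,
       tor_pen = params$weights[["tor"]] * mol$n_tor,
       rigid = length(mol$torsion_tree$branches) == 0,
       ispec = ispec)
}

# fast intra-ligand terms from the cached pair spec; hydrogen-bond-eligible
# intra pairs (rare) still use the exact angular weight
#' @noRd
intra_terms_fast <- function(cache, lxyz, params) {
  mol <- cache$mol
  nl <- nrow(lxyz)
  occ_self <- numeric(nl)
  if (nl > 1) {
    L2 <- outer(lxyz[, 1], lxyz[, 1], "-")^2 + outer(lxyz[, 2], lxyz[, 2], "-")^2 +
      outer(lxyz[, 3], lxyz[, 3], "-")^2
    gl <- exp(-L2 / (2 * params$sigma^2))
    diag(gl) <- 0
    gl[L2 > params$cutoff^2] <- 0
    occ_self <- as.numeric(gl %*% cache$V)
  }
  sp <- cache$ispec
  if (is.null(sp)) return(list(vdw = 0, hb = 0, el = 0, occ_self = occ_self))
  d <- lxyz[sp$i, , drop = FALSE] - lxyz[sp$j, , drop = FALSE]
  r <- sqrt(d[, 1]^2 + d[, 2]^2 + d[, 3]^2)
  ok <- r > 0 & r <= params$cutoff
  e_vdw <- 0; e_hb <- 0; e_el <- 0
  vsel <- ok & !sp$elig
  if (any(vsel)) {
    rs <- smooth_r(r[vsel], sp$Rmin[vsel], params$smooth_width)
    e_vdw <- sum(sp$A[vsel] / rs^12 - sp$B[vsel] / rs^6)
  }
  hsel <- which(ok & sp$elig)
  if (length(hsel) > 0) {
    lp <- ligand_polar_geometry(mol, lxyz)
    for (k in hsel) {
      E <- intra_E(sp$i[k], sp$j[k], lxyz, mol$atoms$hbond_role, lp,
                   params$angular)
      rs <- smooth_r(r[k], params$hbond$r0, params$smooth_width)
      e_hb <- e_hb + E * (sp$C[k] / rs^12 - sp$D[k] / rs^10)
    }
  }
  if (any(ok)) {
    e_el <- sum(sp$qq[ok] / (sigmoidal_dielectric(r[ok], params$dielectric) * r[ok]))
  }
  list(vdw = e_vdw, hb = e_hb, el = e_el, occ_self = occ_self)
}

# intra-ligand terms (vdw/hbond/elec sums, unweighted, plus ligand
# self-occupancy per atom) at given coordinates
#' @noRd
intra_terms <- function(mol, lxyz, params) {
  ti_l <- type_index(params, mol$atoms$type_code)
  e_vdw <- 0; e_hb <- 0; e_el <- 0
  ipairs <- intra_pair_list(mol)
  if (nrow(ipairs) > 0) {
    lp <- ligand_polar_geometry(mol, lxyz)
    q <- mol$atoms$charge
    for (k in seq_len(nrow(ipairs))) {
      i <- ipairs[k, 1]; j <- ipairs[k, 2]
      r <- sqrt(sum((lxyz[i, ] - lxyz[j, ])^2))
      if (r > params$cutoff || r <= 0) next
      if (params$hb_elig[ti_l[i], ti_l[j]]) {
        E <- intra_E(i, j, lxyz, mol$atoms$hbond_role, lp, params$angular)
        rs <- smooth_r(r, params$hbond$r0, params$smooth_width)
        e_hb <- e_hb + E * (params$hbC[ti_l[i], ti_l[j]] / rs^12 -
                            params$hbD[ti_l[i], ti_l[j]] / rs^10)
      } else {
        rs <- smooth_r(r, params$pairRmin[ti_l[i], ti_l[j]], params$smooth_width)
        e_vdw <- e_vdw + params$pairA[ti_l[i], ti_l[j]] / rs^12 -
          params$pairB[ti_l[i], ti_l[j]] / rs^6
      }
      e_el <- e_el + params$coulomb * q[i] * q[j] /
        (sigmoidal_dielectric(r, params$dielectric) * r)
    }
  }
  occ_self <- numeric(nrow(lxyz))
  if (nrow(lxyz) > 1) {
    L2 <- outer(lxyz[, 1], lxyz[, 1], "-")^2 + outer(lxyz[, 2], lxyz[, 2], "-")^2 +
      outer(lxyz[, 3], lxyz[, 3], "-")^2
    gl <- exp(-L2 / (2 * params$sigma^2))
    diag(gl) <- 0
    gl[L2 > params$cutoff^2] <- 0
    occ_self <- as.numeric(gl %*% mol$atoms$V)
  }
  list(vdw = e_vdw, hb = e_hb, el = e_el, occ_self = occ_self)
}

#' Grid-interpolated binding free energy
#'
#' Trilinear interpolation of the affinity, electrostatic and occupancy maps
#' at each ligand atom, plus the exact torsion penalty and exact intra-ligand
#' terms. Agrees with [binding_free_energy()] to within an interpolation
#' error governed by the grid spacing. A pose with any atom outside the box
#' is rejected with an infinite score by default.
#'
#' @param grids a `GridMaps`.
#' @param mol a typed, charged `Molecule`.
#' @param pose a `Pose` (or NULL to score in place).
#' @param params a `ParameterSet`.
#' @param outside one of `"reject"` (default; +Inf total) or `"error"`.
#' @return an `EnergyBreakdown`.
#' @export
grid_energy <- function(grids, mol, pose = NULL, params = default_parameters(),
                        outside = c("reject", "error")) {
  outside <- match.arg(outside)
  if (anyNA(mol$atoms$type_code)) mol <- assign_atom_types(mol, params)
  if (is.null(mol$torsion_tree)) mol <- build_torsion_tree(mol)
  lxyz <- if (is.null(pose)) coords(mol) else realize_pose(mol, pose)
  if (!inside_box(grids, lxyz)) {
    if (outside == "error") stop("ligand atom outside the grid box")
    return(energy_breakdown(vdw = Inf))
  }
  missing_t <- setdiff(unique(mol$atoms$type_code), grids$types)
  if (length(missing_t) > 0) {
    stop("grid maps missing for ligand type(s): ", paste(missing_t, collapse = ", "))
  }
  e_vdw <- 0; e_hb <- 0
  for (tt in unique(mol$atoms$type_code)) {
    idx <- which(mol$atoms$type_code == tt)
    e_vdw <- e_vdw + sum(trilinear(grids$vdw[[tt]], grids$origin, grids$spacing,
                                   grids$dims, lxyz[idx, , drop = FALSE]))
    e_hb <- e_hb + sum(trilinear(grids$hb[[tt]], grids$origin, grids$spacing,
                                 grids$dims, lxyz[idx, , drop = FALSE]))
  }
  e_el <- sum(mol$atoms$charge * trilinear(grids$elec, grids$origin,
                                           grids$spacing, grids$dims, lxyz))
  occ_rec <- trilinear(grids$occ, grids$origin, grids$spacing, grids$dims, lxyz)
  it <- intra_terms(mol, lxyz, params)
  e_sol <- 0
  if (isTRUE(params$use_solvation)) {
    e_sol <- sum(mol$atoms$S * pmax(0, mol$atoms$occmax - occ_rec - it$occ_self))
  }
  W <- params$weights
  energy_breakdown(vdw = W[["vdw"]] * (e_vdw + it$vdw),
                   hbond = W[["hbond"]] * (e_hb + it$hb),
                   elec = W[["elec"]] * (e_el + it$el),
                   torsion = W[["tor"]] * mol$n_tor,
                   desolvation = W[["sol"]] * e_sol)
}

# fast total-only evaluator used inside the search loop; `cache` from
# grid_ligand_cache(); `intra_const` precomputed for rigid ligands
#' @noRd
grid_total_fast <- function(grids, cache, lxyz, params, intra_const = NULL) {
  if (!inside_box(grids, lxyz)) return(Inf)
  pr <- trilinear_prep(grids$origin, grids$spacing, grids$dims, lxyz)
  e_vdw <- 0; e_hb <- 0
  for (tt in names(cache$by_type)) {
    rows <- cache$by_type[[tt]]
    e_vdw <- e_vdw + sum(trilinear_eval(grids$vdw[[tt]], pr, rows))
    e_hb <- e_hb + sum(trilinear_eval(grids$hb[[tt]], pr, rows))
  }
  e_el <- sum(cache$charge * trilinear_eval(grids$elec, pr))
  occ_rec <- trilinear_eval(grids$occ, pr)
  it <- if (!is.null(intra_const)) intra_const else
    intra_terms_fast(cache, lxyz, params)
  e_sol <- if (isTRUE(params$use_solvation))
    sum(cache$S * pmax(0, cache$occmax - occ_rec - it$occ_self)) else 0
  W <- params$weights
  W[["vdw"]] * (e_vdw + it$vdw) + W[["hbond"]] * (e_hb + it$hb) +
    W[["elec"]] * (e_el + it$el) + cache$tor_pen + W[["sol"]] * e_sol
}
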