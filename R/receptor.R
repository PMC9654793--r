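# Receptor model: typed protein atoms with residue bookkeeping, rule-based
# protonation of titratable sidechains, ideal-geometry hydrogen placement,
# and the designated hinge anchor residue used by the screening filter.

#' @noRd
new_receptor <- function(atoms, infer_bonds = TRUE) {
  stopifnot(all(c("element", "name", "resname", "resno", "chain", "x", "y", "z")
                %in% names(atoms)))
  atoms$element <- normalize_element(atoms$element)
  if (is.null(atoms$charge)) atoms$charge <- 0
  if (is.null(atoms$formal_charge)) atoms$formal_charge <- 0
  for (col in c("type_code", "hbond_role")) if (is.null(atoms[[col]])) atoms[[col]] <- NA_character_
  for (col in c("S", "V", "occmax")) if (is.null(atoms[[col]])) atoms[[col]] <- NA_real_
  rownames(atoms) <- NULL
  rec <- list(atoms = atoms, bonds = NULL, residues = NULL,
              protonation = NULL, hinge = NULL)
  class(rec) <- "Receptor"
  if (infer_bonds) rec$bonds <- infer_bonds_by_distance(atoms)
  rec$residues <- index_residues(atoms)
  rec
}

#' @export
print.Receptor <- function(x, ...) {
  cat(sprintf("Receptor: %d atoms, %d residues", nrow(x$atoms), nrow(x$residues)))
  if (!is.null(x$hinge)) {
    cat(sprintf("; hinge %s:%d", x$hinge$chain, x$hinge$resno))
  }
  cat("\n")
  invisible(x)
}

# covalent bonds by interatomic distance (sum of covalent radii + 0.45 A)
#' @noRd
infer_bonds_by_distance <- function(atoms) {
  n <- nrow(atoms)
  if (n < 2) return(data.frame(i = integer(), j = integer(), order = integer()))
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  r <- .COV_RADIUS[atoms$element]
  r[is.na(r)] <- 0.8
  out_i <- integer(0); out_j <- integer(0)
  # chunked pair scan keeps memory bounded for large receptors
  chunk <- 500L
  for (s in seq(1L, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    idx <- s:e
    d2 <- outer(rowSums(xyz[idx, , drop = FALSE]^2), rowSums(xyz^2), "+") -
      2 * xyz[idx, , drop = FALSE] %*% t(xyz)
    lim <- outer(r[idx], r, "+") + 0.45
    hit <- which(d2 < lim^2 & d2 > 0.16, arr.ind = TRUE)
    if (nrow(hit) > 0) {
      gi <- idx[hit[, 1]]; gj <- hit[, 2]
      keep <- gi < gj
      out_i <- c(out_i, gi[keep]); out_j <- c(out_j, gj[keep])
    }
  }
  data.frame(i = out_i, j = out_j, order = 1L)
}

#' @noRd
index_residues <- function(atoms) {
  key <- paste(atoms$chain, atoms$resno, atoms$resname)
  first <- !duplicated(key)
  res <- data.frame(chain = atoms$chain[first], resno = atoms$resno[first],
                    resname = atoms$resname[first], stringsAsFactors = FALSE)
  std <- res$resname %in% names(.RESIDUE_H)
  res$incomplete <- vapply(seq_len(nrow(res)), function(k) {
    if (!std[k]) return(FALSE)
    sel <- atoms$chain == res$chain[k] & atoms$resno == res$resno[k]
    !all(c("N", "CA", "C", "O") %in% atoms$name[sel])
  }, logical(1))
  res
}

#' @noRd
residue_atom_idx <- function(rec, chain, resno) {
  which(rec$atoms$chain == chain & rec$atoms$resno == resno)
}

#' Load a receptor structure from a PDB file
#'
#' Atoms are grouped by residue; alternate locations are resolved to the
#' highest occupancy; waters and hetero groups are dropped unless kept.
#' Covalent connectivity is inferred from interatomic distances.
#'
#' @param path PDB file (single model).
#' @param keep_hetero keep HETATM groups (waters are always dropped).
#' @return a `Receptor`.
#' @export
load_receptor <- function(path, keep_hetero = FALSE) {
  pdb <- tryCatch(bio3d::read.pdb(path), error = function(e) {
    stop("cannot parse PDB file ", path, ": ", conditionMessage(e))
  })
  a <- pdb$atom
  keep <- a$type == "ATOM"
  if (keep_hetero) keep <- keep | (a$type == "HETATM" & !a$resid %in% c("HOH", "WAT"))
  a <- a[keep, , drop = FALSE]
  if (nrow(a) == 0) stop("no protein atoms in ", path)
  # resolve altlocs: keep highest occupancy per (chain, resno, atom name)
  if (any(!is.na(a$alt) & a$alt != "")) {
    key <- paste(a$chain, a$resno, a$insert, a$elety)
    occ <- ifelse(is.na(a$o), 1, a$o)
    ord <- order(key, -occ)
    a <- a[ord, , drop = FALSE]
    a <- a[!duplicated(paste(a$chain, a$resno, a$insert, a$elety)), , drop = FALSE]
    a <- a[order(as.integer(rownames(a))), , drop = FALSE]
  }
  el <- a$elesy
  miss <- is.na(el) | el == ""
  el[miss] <- substr(trimws(a$elety[miss]), 1, 1)
  atoms <- data.frame(element = normalize_element(el), name = trimws(a$elety),
                      resname = a$resid, resno = a$resno,
                      chain = ifelse(is.na(a$chain) | a$chain == "", "A", a$chain),
                      x = a$x, y = a$y, z = a$z, stringsAsFactors = FALSE)
  new_receptor(atoms)
}

# -- protonation ------------------------------------------------------------

# name-based H-bond partner sets used by the protonation rules (heavy atoms
# only; applied before hydrogens exist)
.ACCEPTOR_NAMES <- list(
  any_O = TRUE,
  N = c("ND1", "NE2")   # His sidechain N
)
.DONOR_NAMES <- c("N", "NZ", "NE", "NH1", "NH2", "ND1", "NE2", "NE1",
                  "ND2", "OG", "OG1", "OH", "SG")

#' Assign protonation states of titratable residues
#'
#' Rule-based assignment from the heavy-atom hydrogen-bonding neighborhood:
#' Asp/Glu sidechains are neutral iff either carboxylate oxygen has a
#' hydrogen-bond acceptor atom within `dmax`; Lys is positively charged
#' unless its amine nitrogen lies within `dmax` of a hydrogen-bond donor
#' atom; His follows the same donor-neighborhood criterion, with the neutral
#' tautomer chosen so the nitrogen nearest the donor is the acceptor
#' (N-epsilon-H when ambiguous). Arg is always charged. Decisions are logged
#' per residue in `rec$protonation`.
#'
#' "Pointed toward" is operationalized as a pure heavy-atom distance
#' criterion; `angle_gate` optionally additionally requires the partner to
#' lie at >= 90 degrees from the carboxylate C-O bond (a geometric proxy
#' usable before hydrogens exist).
#'
#' @param rec a `Receptor` with heavy atoms placed.
#' @param dmax neighborhood distance limit, Angstrom (default 3.5).
#' @param angle_gate enable the optional angular gate (default FALSE).
#' @return the receptor with `protonation` filled; idempotent.
#' @export
assign_protonation_states <- function(rec, dmax = 3.5, angle_gate = FALSE) {
  a <- rec$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")])
  is_acc <- a$element == "O" |
    (a$element == "N" & a$name %in% .ACCEPTOR_NAMES$N & a$resname == "HIS")
  is_don <- a$name %in% .DONOR_NAMES &
    ((a$element == "N") | (a$element == "O") | (a$element == "S"))
  res <- rec$residues
  log <- list()
  near_partner <- function(o_idx, partner_mask, cres) {
    # nearest partner atom outside the residue itself
    cand <- which(partner_mask)
    cand <- cand[!(a$chain[cand] == a$chain[o_idx][1] &
                   a$resno[cand] == a$resno[o_idx][1])]
    if (length(cand) == 0 || length(o_idx) == 0) return(Inf)
    d <- sqrt(outer(rowSums(xyz[o_idx, , drop = FALSE]^2), rowSums(xyz[cand, , drop = FALSE]^2), "+") -
              2 * xyz[o_idx, , drop = FALSE] %*% t(xyz[cand, , drop = FALSE]))
    if (angle_gate && !is.null(cres)) {
      # partner must lie at >= 90 deg from the C-O bond at the oxygen
      for (oi in seq_along(o_idx)) {
        u <- xyz[cres, ] - xyz[o_idx[oi], ]
        for (ci in seq_along(cand)) {
          v <- xyz[cand[ci], ] - xyz[o_idx[oi], ]
          cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
          if (cosang > 0) d[oi, ci] <- Inf   # < 90 deg: pointing away
        }
      }
    }
    min(d)
  }
  for (k in seq_len(nrow(res))) {
    rn <- res$resname[k]
    if (!rn %in% c("ASP", "GLU", "LYS", "HIS", "ARG")) next
    idx <- residue_atom_idx(rec, res$chain[k], res$resno[k])
    nm <- a$name[idx]
    entry <- NULL
    if (rn %in% c("ASP", "GLU")) {
      onames <- if (rn == "ASP") c("OD1", "OD2") else c("OE1", "OE2")
      cname <- if (rn == "ASP") "CG" else "CD"
      o_idx <- idx[nm %in% onames]
      cres <- idx[nm == cname][1]
      dmin <- near_partner(o_idx, is_acc, cres)
      neutral <- is.finite(dmin) && dmin <= dmax
      entry <- data.frame(state = if (neutral) "neutral" else "charged",
                          tautomer = "",
                          reason = if (neutral)
                            sprintf("acceptor at %.2f A <= %.2f A", dmin, dmax)
                          else sprintf("nearest acceptor %.2f A > %.2f A",
                                       min(dmin, 999), dmax))
    } else if (rn == "LYS") {
      nz <- idx[nm == "NZ"]
      dmin <- near_partner(nz, is_don, NULL)
      neutral <- is.finite(dmin) && dmin <= dmax
      entry <- data.frame(state = if (neutral) "neutral" else "charged",
                          tautomer = "",
                          reason = if (neutral)
                            sprintf("donor at %.2f A <= %.2f A", dmin, dmax)
                          else "no donor in neighborhood")
    } else if (rn == "HIS") {
      nd <- idx[nm == "ND1"]; ne <- idx[nm == "NE2"]
      d_nd <- near_partner(nd, is_don, NULL)
      d_ne <- near_partner(ne, is_don, NULL)
      neutral <- min(d_nd, d_ne) <= dmax
      taut <- if (!neutral) "" else if (d_ne < d_nd) "Nd-H" else "Ne-H"
      entry <- data.frame(state = if (neutral) "neutral" else "charged",
                          tautomer = taut,
                          reason = if (neutral)
                            sprintf("donor near %s (%.2f A)",
                                    if (d_ne < d_nd) "NE2" else "ND1",
                                    min(d_nd, d_ne))
                          else "no donor in neighborhood (default +)")
    } else if (rn == "ARG") {
      entry <- data.frame(state = "charged", tautomer = "",
                          reason = "Arg always charged")
    }
    entry$chain <- res$chain[k]; entry$resno <- res$resno[k]; entry$resname <- rn
    log[[length(log) + 1]] <- entry
  }
  rec$protonation <- if (length(log) > 0) {
    do.call(rbind, log)[, c("chain", "resno", "resname", "state", "tautomer", "reason")]
  } else {
    data.frame(chain = character(), resno = integer(), resname = character(),
               state = character(), tautomer = character(), reason = character())
  }
  rec
}

# -- hydrogen placement -----------------------------------------------------

# sidechain hydrogen counts per standard residue: name -> c(nH, sp) where
# sp is 3 or 2; backbone N/CA handled separately. Protonation-dependent
# entries (Asp OD2, Glu OE2, Lys NZ, His ND1/NE2) are adjusted at run time.
.RESIDUE_H <- list(
  ALA = list(CB = c(3, 3)),
  ARG = list(CB = c(2, 3), CG = c(2, 3), CD = c(2, 3), NE = c(1, 2),
             NH1 = c(2, 2), NH2 = c(2, 2)),
  ASN = list(CB = c(2, 3), ND2 = c(2, 2)),
  ASP = list(CB = c(2, 3)),
  CYS = list(CB = c(2, 3), SG = c(1, 3)),
  GLN = list(CB = c(2, 3), CG = c(2, 3), NE2 = c(2, 2)),
  GLU = list(CB = c(2, 3), CG = c(2, 3)),
  GLY = list(),
  HIS = list(CB = c(2, 3), CD2 = c(1, 2), CE1 = c(1, 2)),
  ILE = list(CB = c(1, 3), CG1 = c(2, 3), CG2 = c(3, 3), CD1 = c(3, 3)),
  LEU = list(CB = c(2, 3), CG = c(1, 3), CD1 = c(3, 3), CD2 = c(3, 3)),
  LYS = list(CB = c(2, 3), CG = c(2, 3), CD = c(2, 3), CE = c(2, 3)),
  MET = list(CB = c(2, 3), CG = c(2, 3), CE = c(3, 3)),
  PHE = list(CB = c(2, 3), CD1 = c(1, 2), CD2 = c(1, 2), CE1 = c(1, 2),
             CE2 = c(1, 2), CZ = c(1, 2)),
  PRO = list(CB = c(2, 3), CG = c(2, 3), CD = c(2, 3)),
  SER = list(CB = c(2, 3), OG = c(1, 3)),
  THR = list(CB = c(1, 3), OG1 = c(1, 3), CG2 = c(3, 3)),
  TRP = list(CB = c(2, 3), CD1 = c(1, 2), NE1 = c(1, 2), CE3 = c(1, 2),
             CZ2 = c(1, 2), CZ3 = c(1, 2), CH2 = c(1, 2)),
  TYR = list(CB = c(2, 3), CD1 = c(1, 2), CD2 = c(1, 2), CE1 = c(1, 2),
             CE2 = c(1, 2), OH = c(1, 3)),
  VAL = list(CB = c(1, 3), CG1 = c(3, 3), CG2 = c(3, 3))
)

.H_BOND_LENGTH <- c(C = 1.09, N = 1.01, O = 0.96, S = 1.34)

#' @noRd
unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) c(1, 0, 0) else v / n
}

#' @noRd
any_perp <- function(u) {
  v <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  unit3(v - sum(v * u) * u)
}

#' @noRd
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

# ideal-geometry H positions for a heavy atom at `pos` with placed heavy
# neighbors `nbrs` (matrix, possibly 0 rows), `ref` an optional reference
# position beyond the first neighbor (defines torsion phase)
#' @noRd
ideal_h_positions <- function(pos, nbrs, n_h, sp, L, ref = NULL) {
  m <- nrow(nbrs)
  out <- matrix(numeric(0), 0, 3)
  if (n_h == 0) return(out)
  if (m == 0) {
    dirs <- rbind(c(1, 0, 0), c(-1/3, 2*sqrt(2)/3, 0),
                  c(-1/3, -sqrt(2)/3, sqrt(6)/3), c(-1/3, -sqrt(2)/3, -sqrt(6)/3))
    return(matrix(pos, n_h, 3, byrow = TRUE) + L * dirs[seq_len(n_h), , drop = FALSE])
  }
  if (m >= 3) {
    d <- -unit3(colSums(t(apply(nbrs, 1, function(p) unit3(p - pos)))))
    return(matrix(pos + L * d, 1, 3))
  }
  if (m == 2) {
    b1 <- unit3(nbrs[1, ] - pos); b2 <- unit3(nbrs[2, ] - pos)
    bis <- -unit3(b1 + b2)
    nrm <- cross3(b1, b2)
    nrm <- if (sqrt(sum(nrm^2)) < 1e-8) any_perp(b1) else unit3(nrm)
    if (n_h == 1) return(matrix(pos + L * bis, 1, 3))
    half <- 54.75 * pi / 180
    return(rbind(pos + L * unit3(bis * cos(half) + nrm * sin(half)),
                 pos + L * unit3(bis * cos(half) - nrm * sin(half))))
  }
  # m == 1
  u <- unit3(nbrs[1, ] - pos)
  e <- if (!is.null(ref)) {
    w <- ref - nbrs[1, ]
    pe <- w - sum(w * u) * u
    if (sqrt(sum(pe^2)) < 1e-8) any_perp(u) else unit3(pe)
  } else any_perp(u)
  f <- unit3(cross3(u, e))
  alpha <- if (sp == 2) 120 else 109.47
  a <- alpha * pi / 180
  dir_at <- function(phi) {
    ph <- phi * pi / 180
    unit3(u * cos(a) + (e * cos(ph) + f * sin(ph)) * sin(a))
  }
  phis <- if (sp == 2) c(180, 0) else c(180, 60, 300)
  do.call(rbind, lapply(phis[seq_len(n_h)], function(ph) pos + L * dir_at(ph)))
}

#' Add hydrogens at ideal geometry
#'
#' Hydrogens are placed on every heavy atom of standard residues consistent
#' with the assigned protonation states (neutral Asp/Glu gain one carboxyl H
#' on OD2/OE2; charged Lys carries 3 amine H; His gains ring N-H per
#' tautomer). Placement uses ideal internal coordinates; no minimization.
#' Residues missing backbone atoms are skipped with a warning.
#'
#' @param rec a `Receptor` with protonation states assigned
#'   (see [assign_protonation_states()]; run automatically if missing).
#' @return the receptor with H atoms appended and bonds re-inferred.
#' @export
add_hydrogens <- function(rec) {
  if (is.null(rec$protonation)) rec <- assign_protonation_states(rec)
  a <- rec$atoms
  if (any(a$element == "H")) return(rec)   # already protonated
  xyz <- as.matrix(a[, c("x", "y", "z")])
  nb <- vector("list", nrow(a))
  for (k in seq_len(nrow(rec$bonds))) {
    i <- rec$bonds$i[k]; j <- rec$bonds$j[k]
    nb[[i]] <- c(nb[[i]], j); nb[[j]] <- c(nb[[j]], i)
  }
  prot <- rec$protonation
  state_of <- function(ch, rn) {
    hit <- which(prot$chain == ch & prot$resno == rn)
    if (length(hit) == 0) list(state = NA, taut = "") else
      list(state = prot$state[hit[1]], taut = prot$tautomer[hit[1]])
  }
  newH <- list()
  add <- function(parent, hpos) {
    for (r in seq_len(nrow(hpos))) {
      newH[[length(newH) + 1]] <<- data.frame(
        element = "H", name = paste0("H", a$name[parent]),
        resname = a$resname[parent], resno = a$resno[parent],
        chain = a$chain[parent], x = hpos[r, 1], y = hpos[r, 2], z = hpos[r, 3],
        stringsAsFactors = FALSE)
    }
  }
  res <- rec$residues
  for (k in seq_len(nrow(res))) {
    rn <- res$resname[k]
    if (!rn %in% names(.RESIDUE_H)) next
    if (res$incomplete[k]) {
      warning("residue ", rn, " ", res$chain[k], res$resno[k],
              " incomplete; hydrogens skipped")
      next
    }
    idx <- residue_atom_idx(rec, res$chain[k], res$resno[k])
    nm <- a$name[idx]
    st <- state_of(res$chain[k], res$resno[k])
    spec <- .RESIDUE_H[[rn]]
    # protonation-dependent additions
    if (rn == "ASP" && identical(st$state, "neutral")) spec$OD2 <- c(1, 3)
    if (rn == "GLU" && identical(st$state, "neutral")) spec$OE2 <- c(1, 3)
    if (rn == "LYS") spec$NZ <- if (identical(st$state, "neutral")) c(2, 3) else c(3, 3)
    if (rn == "HIS") {
      if (identical(st$state, "charged")) {
        spec$ND1 <- c(1, 2); spec$NE2 <- c(1, 2)
      } else if (identical(st$taut, "Nd-H")) spec$ND1 <- c(1, 2)
      else spec$NE2 <- c(1, 2)
    }
    # backbone
    spec$N <- if (rn == "PRO") NULL else c(1, 2)
    spec$CA <- if (rn == "GLY") c(2, 3) else c(1, 3)
    for (an in names(spec)) {
      ai <- idx[nm == an]
      if (length(ai) != 1) next
      heavy_nb <- nb[[ai]]
      heavy_nb <- heavy_nb[a$element[heavy_nb] != "H"]
      ref <- NULL
      if (length(heavy_nb) == 1) {
        beyond <- setdiff(nb[[heavy_nb[1]]], ai)
        beyond <- beyond[a$element[beyond] != "H"]
        if (length(beyond) > 0) ref <- xyz[beyond[1], ]
      }
      L <- .H_BOND_LENGTH[a$element[ai]]
      if (is.na(L)) L <- 1.0
      hp <- ideal_h_positions(xyz[ai, ], xyz[heavy_nb, , drop = FALSE],
                              spec[[an]][1], spec[[an]][2], L, ref)
      add(ai, hp)
    }
  }
  if (length(newH) > 0) {
    hdf <- do.call(rbind, newH)
    hdf$charge <- 0; hdf$formal_charge <- 0
    hdf$type_code <- NA_character_; hdf$hbond_role <- NA_character_
    hdf$S <- NA_real_; hdf$V <- NA_real_; hdf$occmax <- NA_real_
    rec$atoms <- rbind(a, hdf[, names(a)])
  }
  rec$bonds <- infer_bonds_by_distance(rec$atoms)
  rec$residues <- index_residues(rec$atoms)
  # keep hinge atom handles valid (heavy-atom indices unchanged by rbind)
  if (!is.null(rec$hinge)) rec <- designate_hinge_residue(rec, rec$hinge$chain, rec$hinge$resno)
  rec
}

#' Designate the hinge anchor residue
#'
#' Caches handles to the backbone amide N (+ its H when present) and the
#' backbone carbonyl O of the named residue; the screening filter tests
#' ligand polar atoms against exactly these two backbone groups.
#'
#' @param rec a `Receptor`.
#' @param chain chain identifier.
#' @param resnum residue number.
#' @return the receptor with `hinge` set.
#' @export
designate_hinge_residue <- function(rec, chain, resnum) {
  idx <- residue_atom_idx(rec, chain, resnum)
  if (length(idx) == 0) {
    rng <- range(rec$atoms$resno)
    stop("residue ", chain, ":", resnum, " not found (available residues ",
         rng[1], "..", rng[2], ")")
  }
  nm <- rec$atoms$name[idx]
  n_idx <- idx[nm == "N"]; o_idx <- idx[nm == "O"]
  if (length(n_idx) != 1) stop("hinge residue ", chain, ":", resnum,
                               " lacks backbone atom N")
  if (length(o_idx) != 1) stop("hinge residue ", chain, ":", resnum,
                               " lacks backbone atom O")
  # amide H: an H bonded to the backbone N
  h_idx <- integer(0)
  if (!is.null(rec$bonds) && nrow(rec$bonds) > 0) {
    cand <- c(rec$bonds$j[rec$bonds$i == n_idx], rec$bonds$i[rec$bonds$j == n_idx])
    h_idx <- cand[rec$atoms$element[cand] == "H"]
  }
  rec$hinge <- list(chain = chain, resno = resnum, N = n_idx, O = o_idx,
                    H = if (length(h_idx) > 0) h_idx[1] else NA_integer_)
  rec
}

# -- typing & charges -------------------------------------------------------

.AROMATIC_SC <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2")
)

#' Type and charge a prepared receptor
#'
#' Assigns force-field atom types, hydrogen-bond roles and solvation
#' parameters (same rules as the ligand side), then computes partial charges
#' with the PEOE scheme seeded by the formal charges implied by the assigned
#' protonation states (+1 Lys/Arg/His+, -1 charged Asp/Glu).
#'
#' @param rec a protonated `Receptor` (after [add_hydrogens()]).
#' @param params a `ParameterSet`.
#' @return the receptor with `type_code`, `hbond_role`, solvation columns and
#'   `charge` populated, plus cached polar geometry for the scoring terms.
#' @export
type_receptor <- function(rec, params = default_parameters()) {
  a <- rec$atoms
  arom <- rep(FALSE, nrow(a))
  for (rn in names(.AROMATIC_SC)) {
    arom <- arom | (a$resname == rn & a$name %in% .AROMATIC_SC[[rn]])
  }
  rec$atoms <- type_atoms_impl(a, rec$bonds, arom, params)
  # formal charge seeds from protonation states
  fc <- numeric(nrow(a))
  if (!is.null(rec$protonation)) {
    p <- rec$protonation
    for (k in seq_len(nrow(p))) {
      idx <- residue_atom_idx(rec, p$chain[k], p$resno[k])
      nm <- rec$atoms$name[idx]
      if (p$resname[k] == "LYS" && p$state[k] == "charged") fc[idx[nm == "NZ"]] <- 1
      if (p$resname[k] == "ARG") fc[idx[nm == "CZ"]] <- 1
      if (p$resname[k] == "HIS" && p$state[k] == "charged") fc[idx[nm == "NE2"]] <- 1
      if (p$resname[k] == "ASP" && p$state[k] == "charged") fc[idx[nm == "OD1"]] <- -1
      if (p$resname[k] == "GLU" && p$state[k] == "charged") fc[idx[nm == "OE1"]] <- -1
    }
  }
  rec$atoms$formal_charge <- fc
  pseudo <- list(name = "receptor", atoms = rec$atoms, bonds = rec$bonds)
  class(pseudo) <- "Molecule"
  charged <- tryCatch(gasteiger_charges(pseudo),
                      error = function(e) { pseudo$atoms$charge <- fc; pseudo })
  rec$atoms$charge <- charged$atoms$charge
  rec$polar <- receptor_polar_geometry(rec)
  rec
}

# cache donor H indices and acceptor lone-pair axes for directional H-bonds;
# both depend only on receptor geometry, so the affinity maps can bake in
# the angular weight exactly
#' @noRd
receptor_polar_geometry <- function(rec) {
  a <- rec$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")])
  n <- nrow(a)
  nb <- vector("list", n)
  for (k in seq_len(nrow(rec$bonds))) {
    i <- rec$bonds$i[k]; j <- rec$bonds$j[k]
    nb[[i]] <- c(nb[[i]], j); nb[[j]] <- c(nb[[j]], i)
  }
  don_h <- vector("list", n)
  acc_dir <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    role <- a$hbond_role[i]
    if (is.na(role)) next
    if (is_donor_heavy(role)) {
      hs <- nb[[i]][a$element[nb[[i]]] == "H"]
      if (length(hs) > 0) don_h[[i]] <- hs
    }
    if (is_acceptor(role)) {
      heavy <- nb[[i]][a$element[nb[[i]]] != "H"]
      if (length(heavy) > 0) {
        s <- colSums(matrix(t(apply(xyz[heavy, , drop = FALSE], 1,
                                    function(p) unit3(p - xyz[i, ]))),
                            ncol = 3))
        acc_dir[i, ] <- -unit3(s)
      }
    }
  }
  list(don_h = don_h, acc_dir = acc_dir)
}

#' One-call receptor preparation
#'
#' [load_receptor()] (or an in-memory receptor) -> protonation rules ->
#' hydrogen placement -> typing/charging -> hinge designation.
#'
#' @param x path to a PDB file or a `Receptor`.
#' @param hinge optional `c(chain, resnum)` hinge designation.
#' @param params a `ParameterSet`.
#' @param dmax protonation neighborhood limit, Angstrom.
#' @return a fully prepared `Receptor`.
#' @export
prepare_receptor <- function(x, hinge = NULL, params = default_parameters(),
                             dmax = 3.5) {
  rec <- if (inherits(x, "Receptor")) x else load_receptor(x)
  rec <- assign_protonation_states(rec, dmax = dmax)
  rec <- add_hydrogens(rec)
  rec <- type_receptor(rec, params)
  if (!is.null(hinge)) {
    rec <- designate_hinge_residue(rec, hinge[1], as.integer(hinge[2]))
  }
  rec
}

#' Total formal charge implied by the assigned protonation states
#' @param rec a `Receptor` with protonation assigned.
#' @return integer net charge.
#' @export
receptor_formal_charge <- function(rec) {
  if (is.null(rec$protonation)) stop("protonation states not assigned")
  p <- rec$protonation
  sum(ifelse(p$state == "charged",
             ifelse(p$resname %in% c("ASP", "GLU"), -1L, 1L), 0L))
}
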