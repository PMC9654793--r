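#' Gasteiger-Marsili partial charges (PEOE)
#'
#' Iterative partial equalization of orbital electronegativity: each atom's
#' electronegativity is `chi(q) = a + b q + c q^2`; along every bond, charge
#' flows from the less to the more electronegative atom, scaled by the cation
#' electronegativity of the donor and damped by `damping^iteration`. The
#' canonical schedule (8 rounds, damping factor halved per round, i.e.
#' 0.5, 0.25, ...) is run with an additional convergence check at 1e-6
#' maximum charge change. Total charge is conserved exactly; formal charges
#' seed the iteration.
#'
#' @param mol a `Molecule` with explicit hydrogens.
#' @param n_iter iteration count.
#' @param damping per-round geometric damping factor.
#' @param tol early-exit tolerance on the max per-round charge change, e.
#' @return the molecule with `atoms$charge` set.
#' @export
gasteiger_charges <- function(mol, n_iter = 8, damping = 0.5, tol = 1e-6) {
  n <- nrow(mol$atoms)
  el <- mol$atoms$element
  key <- peoe_key(mol)
  bad <- which(!key %in% rownames(.PEOE_PARAMS))
  if (length(bad) > 0) {
    stop("element(s) outside the PEOE electronegativity table: ",
         paste(unique(el[bad]), collapse = ", "))
  }
  a <- .PEOE_PARAMS[key, "a"]; b <- .PEOE_PARAMS[key, "b"]; cc <- .PEOE_PARAMS[key, "c"]
  # cation electronegativity chi(+1); hydrogen uses the special value 20.02
  chi_plus <- a + b + cc
  chi_plus[el == "H"] <- 20.02
  q <- as.numeric(mol$atoms$formal_charge)
  bi <- mol$bonds$i; bj <- mol$bonds$j
  f <- damping
  for (it in seq_len(n_iter)) {
    chi <- a + b * q + cc * q^2
    dq <- numeric(n)
    for (k in seq_along(bi)) {
      i <- bi[k]; j <- bj[k]
      if (chi[i] < chi[j]) {
        t <- (chi[j] - chi[i]) / chi_plus[i] * f
        dq[i] <- dq[i] + t; dq[j] <- dq[j] - t
      } else if (chi[j] < chi[i]) {
        t <- (chi[i] - chi[j]) / chi_plus[j] * f
        dq[j] <- dq[j] + t; dq[i] <- dq[i] - t
      }
    }
    q <- q + dq
    if (max(abs(dq)) < tol) break
    f <- f * damping
  }
  mol$atoms$charge <- q
  mol
}

# element + hybridisation bucket for the PEOE table
#' @noRd
peoe_key <- function(mol) {
  n <- nrow(mol$atoms)
  el <- mol$atoms$element
  maxord <- rep(1L, n)
  ndouble <- rep(0L, n)
  for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[k]; j <- mol$bonds$j[k]; o <- mol$bonds$order[k]
    oo <- if (o == 4L) 2L else o   # aromatic counts as conjugated
    maxord[c(i, j)] <- pmax(maxord[c(i, j)], oo)
    if (oo == 2L) { ndouble[i] <- ndouble[i] + 1L; ndouble[j] <- ndouble[j] + 1L }
  }
  arom <- aromatic_atoms(mol)
  hyb <- ifelse(maxord >= 3 | ndouble >= 2, "sp",
                ifelse(maxord == 2 | arom, "sp2", "sp3"))
  ifelse(el %in% c("H", "F", "Cl", "Br", "I"), el, paste(el, hyb, sep = "."))
}
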