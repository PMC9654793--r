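# Physicochemical descriptors and the Rule-of-Five druggability filter.

# implicit hydrogen count per atom (0 when hydrogens are explicit and the
# atom's valence is satisfied); aromatic bond order 4 counts 1.5
#' @noRd
implicit_h <- function(mol) {
  n <- nrow(mol$atoms)
  el <- mol$atoms$element
  val <- .DEFAULT_VALENCE[el]
  val[is.na(val)] <- 0
  used <- numeric(n)
  for (k in seq_len(nrow(mol$bonds))) {
    o <- mol$bonds$order[k]
    oo <- if (o == 4) 1.5 else o
    used[mol$bonds$i[k]] <- used[mol$bonds$i[k]] + oo
    used[mol$bonds$j[k]] <- used[mol$bonds$j[k]] + oo
  }
  fc <- mol$atoms$formal_charge
  val_eff <- val + ifelse(el %in% c("N", "P"), fc, -abs(fc))
  pmax(0, round(val_eff - used))
}

#' Molecular weight
#'
#' Sum of standard average atomic masses over all atoms, hydrogens included;
#' hydrogens missing from the record are completed from default valences.
#'
#' @param mol a `Molecule`.
#' @return mass in amu.
#' @export
molecular_weight <- function(mol) {
  m <- sum(element_mass(mol$atoms$element))
  m + sum(implicit_h(mol)) * .ATOMIC_MASS[["H"]]
}

#' @noRd
count_hbd <- function(mol) {
  # Lipinski donors: O-H and N-H hydrogens (explicit + implicit)
  el <- mol$atoms$element
  imp <- implicit_h(mol)
  nb <- neighbor_list(mol)
  expl <- vapply(seq_len(nrow(mol$atoms)), function(i) {
    if (!el[i] %in% c("N", "O")) return(0L)
    sum(el[nb[[i]]] == "H")
  }, integer(1))
  sum(expl) + sum(imp[el %in% c("N", "O")])
}

#' @noRd
count_hba <- function(mol) sum(mol$atoms$element %in% c("N", "O"))

#' Crude additive atomic-contribution logP
#'
#' Heavy-atom additive estimate (aromatic C +0.3, aliphatic C +0.5, N -1.0,
#' O -0.7, S +0.5, F +0.2, Cl +0.7, Br +0.9, I +1.1, P -0.5). Deliberately
#' coarse: it only has to separate grossly greasy molecules from drug-like
#' ones for the Rule-of-Five gate, and the method name is recorded in the
#' `ParameterSet` so the filter dialect is auditable.
#'
#' @param mol a `Molecule`.
#' @return estimated octanol/water logP.
#' @export
logp_estimate <- function(mol) {
  contrib <- c(C_arom = 0.3, C = 0.5, N = -1.0, O = -0.7, S = 0.5,
               F = 0.2, Cl = 0.7, Br = 0.9, I = 1.1, P = -0.5)
  arom <- aromatic_atoms(mol)
  el <- mol$atoms$element
  v <- ifelse(el == "C" & arom, contrib["C_arom"],
              ifelse(el %in% names(contrib), contrib[el], 0))
  sum(v, na.rm = TRUE)
}

#' Rule-of-Five druggability filter
#'
#' Evaluates MW <= 500, H-bond donors (O-H/N-H count) <= 5, H-bond acceptors
#' (N + O count) <= 10 and logP <= 5 (via [logp_estimate()]). Following the
#' common convention, a molecule passes when at most one rule is violated.
#'
#' @param mol a `Molecule` (hydrogens explicit or inferable).
#' @param params `ParameterSet`; its `logp_method` is echoed in the verdict.
#' @return a `FilterVerdict`: list with `passed`, `violations` (character),
#'   and `descriptor_values` (named numeric MW/HBD/HBA/logP).
#' @export
rule_of_five <- function(mol, params = default_parameters()) {
  vals <- c(MW = molecular_weight(mol), HBD = count_hbd(mol),
            HBA = count_hba(mol), logP = logp_estimate(mol))
  lim <- c(MW = 500, HBD = 5, HBA = 10, logP = 5)
  viol <- names(lim)[vals > lim]
  out <- list(passed = length(viol) <= 1, violations = viol,
              descriptor_values = vals, logp_method = params$logp_method)
  class(out) <- "FilterVerdict"
  out
}

#' @export
print.FilterVerdict <- function(x, ...) {
  cat(sprintf("Rule-of-Five: %s (%d violation(s)%s)\n",
              if (x$passed) "PASS" else "FAIL", length(x$violations),
              if (length(x$violations)) paste0(": ", paste(x$violations, collapse = ", ")) else ""))
  print(round(x$descriptor_values, 2))
  invisible(x)
}

#' Tabulate descriptors for a set of molecules
#'
#' @param mols list of `Molecule`s.
#' @param path optional TSV output path (id, MW, HBD, HBA, logP, n_tor, verdict).
#' @param params a `ParameterSet`.
#' @return the descriptor data.frame, invisibly when `path` is given.
#' @export
export_descriptors <- function(mols, path = NULL, params = default_parameters()) {
  rows <- lapply(mols, function(m) {
    v <- rule_of_five(m, params)
    nt <- count_rotatable_bonds(m)
    data.frame(id = m$name, MW = v$descriptor_values[["MW"]],
               HBD = v$descriptor_values[["HBD"]], HBA = v$descriptor_values[["HBA"]],
               logP = v$descriptor_values[["logP"]], n_tor = nt,
               verdict = if (v$passed) "pass" else "fail")
  })
  out <- do.call(rbind, rows)
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}
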