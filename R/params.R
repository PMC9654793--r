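#' Scoring-function parameter set
#'
#' Container for every constant of the five-term binding free energy score:
#' term weights, per-type 12-6 van der Waals parameters, 12-10 hydrogen-bond
#' well parameters, the angular directionality weight, the sigmoidal
#' distance-dependent dielectric, and the solvent-contact (dehydration)
#' parameters `S` (atomic solvation energy per unit volume, kcal/(mol A^3)),
#' `V` (fragmental atomic volume, A^3) and `occmax` (maximum occupancy, A^3)
#' per atom type, together with the Gaussian width `sigma` (A).
#'
#' The shipped defaults are a generic, documented parameterization (classic
#' free-energy-calibrated docking weights; published sigmoidal-dielectric
#' constants; placeholder solvation table built from Bondi volumes). They are
#' data, not code: every entry can be edited or replaced via
#' [read_parameter_table()] / [write_parameter_table()] or directly in the
#' returned list, and `provenance` records where the numbers came from.
#'
#' @param weights named numeric vector with entries `vdw`, `hbond`, `elec`,
#'   `tor`, `sol` (dimensionless, all >= 0).
#' @param sigma Gaussian width of the occupancy kernel, Angstrom.
#' @param cutoff nonbonded pair cutoff, Angstrom.
#' @param logp_method name of the atomic-contribution logP estimator used by
#'   [rule_of_five()] (recorded so the filter dialect is auditable).
#' @return an object of class `ParameterSet`.
#' @export
default_parameters <- function(weights = c(vdw = 0.1485, hbond = 0.0656,
                                           elec = 0.1146, tor = 0.3113,
                                           sol = 0.1711),
                               sigma = 3.5, cutoff = 12.0,
                               logp_method = "additive-fragment (built-in)") {
  stopifnot(all(c("vdw", "hbond", "elec", "tor", "sol") %in% names(weights)),
            all(weights >= 0), sigma > 0, cutoff > 0)

  # atom type table: code, element class, vdW Rii (sum radius at minimum, A),
  # eps (well depth, kcal/mol), H-bond donor/acceptor eligibility, solvation
  # S (kcal/(mol A^3)), V (A^3), occmax (A^3).
  types <- data.frame(
    code   = c("C", "A", "H", "HD", "N", "ND", "NDA", "OA", "ODA",
               "SA", "SH", "F", "CL", "BR", "I", "P"),
    rii    = c(4.00, 4.00, 2.00, 2.00, 3.50, 3.50, 3.50, 3.20, 3.20,
               4.00, 4.00, 3.09, 4.09, 4.33, 4.72, 4.20),
    eps    = c(0.150, 0.150, 0.020, 0.020, 0.160, 0.160, 0.160, 0.200, 0.200,
               0.200, 0.200, 0.080, 0.276, 0.389, 0.550, 0.200),
    donor  = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, FALSE, TRUE,
               FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    acceptor = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, TRUE, TRUE, TRUE,
                 TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    S      = c(0.0040, 0.0035, 0.0000, 0.0000, -0.0060, -0.0060, -0.0060,
               -0.0085, -0.0085, 0.0020, 0.0020, 0.0020, 0.0030, 0.0030,
               0.0030, 0.0010),
    V      = c(20.58, 20.58, 7.24, 7.24, 15.60, 15.60, 15.60, 14.71, 14.71,
               24.43, 24.43, 13.31, 22.45, 26.52, 32.52, 24.43),
    # placeholder maximum occupancy ~ 14 x fragmental volume: the Gaussian
    # kernel at sigma = 3.5 A integrates neighbors out to ~8 A, so a buried
    # atom accumulates a few hundred A^3 of weighted volume; occmax is set
    # above the partial-burial range so the deficit discriminates burial
    occmax = c(288, 288, 101, 101, 218, 218, 218, 206, 206,
               342, 342, 186, 314, 371, 455, 342),
    stringsAsFactors = FALSE
  )
  rownames(types) <- types$code

  p <- list(
    weights = weights[c("vdw", "hbond", "elec", "tor", "sol")],
    types = types,
    # 12-10 H-bond well between donor heavy atom and acceptor heavy atom
    hbond = list(r0 = 2.90, eps = 5.00),
    angular = list(ideal_deg = 180, exponent = 2),
    dielectric = list(eps_bulk = 78.4, lambda = 0.003627,
                      k = 7.7839, A = -8.5525),
    sigma = sigma,
    coulomb = 332.06,
    cutoff = cutoff,
    hard_clash = 1.2,
    # pairwise well smoothing (full width, A): the 12-6 / 12-10 radial
    # profiles are evaluated at the distance clamped to within half this
    # width of the pair minimum, flattening the well bottom (the classic
    # docking-engine treatment; also keeps grid interpolation faithful)
    smooth_width = 0.5,
    logp_method = logp_method,
    use_solvation = TRUE,
    provenance = paste(
      "generic placeholder parameterization: free-energy-calibrated docking",
      "weights; Mehler-Solmajer sigmoidal dielectric constants; documented",
      "placeholder solvation table (not the fitted solvent-contact model",
      "parameters, which are unpublished)")
  )
  class(p) <- "ParameterSet"
  rebuild_pair_tables(p)
}

# Precompute symmetric pair-coefficient matrices over the type table:
# Lorentz-Berthelot style combination for 12-6 (A = eps R^12, B = 2 eps R^6)
# and a single 12-10 well (C = 5 eps r0^12, D = 6 eps r0^10) on eligible
# donor/acceptor pairs.
#' @noRd
rebuild_pair_tables <- function(p) {
  t <- p$types
  n <- nrow(t)
  rij <- outer(t$rii, t$rii, function(a, b) (a + b) / 2)
  eij <- sqrt(outer(t$eps, t$eps))
  p$pairA <- eij * rij^12
  p$pairB <- 2 * eij * rij^6
  dimnames(p$pairA) <- dimnames(p$pairB) <- list(t$code, t$code)
  p$pairRmin <- rij
  elig <- outer(t$donor, t$acceptor, "&") | outer(t$acceptor, t$donor, "&")
  p$hb_elig <- elig
  # polar hydrogens interact with acceptors only through the H-bond term of
  # their parent donor: zero their 12-6 coefficients against acceptors
  hd <- t$code == "HD"
  excl <- outer(hd, t$acceptor, "&") | outer(t$acceptor, hd, "&")
  p$pairA[excl] <- 0
  p$pairB[excl] <- 0
  p$hbC <- matrix(5 * p$hbond$eps * p$hbond$r0^12, n, n) * elig
  p$hbD <- matrix(6 * p$hbond$eps * p$hbond$r0^10, n, n) * elig
  dimnames(p$pairA) <- dimnames(p$pairB) <- dimnames(p$hb_elig) <-
    dimnames(p$hbC) <- dimnames(p$hbD) <- list(t$code, t$code)
  p
}

#' Sigmoidal distance-dependent dielectric
#'
#' `eps(r) = A + B / (1 + k exp(-lambda B r))` with `B = eps_bulk - A`:
#' protein-interior-like values at short range rising monotonically to bulk
#' water's permittivity at long range.
#'
#' @param r distance(s), Angstrom.
#' @param dielectric constants list (`eps_bulk`, `lambda`, `k`, `A`).
#' @return dielectric value(s), dimensionless.
#' @export
sigmoidal_dielectric <- function(r, dielectric = default_parameters()$dielectric) {
  B <- dielectric$eps_bulk - dielectric$A
  dielectric$A + B / (1 + dielectric$k * exp(-dielectric$lambda * B * r))
}

#' @noRd
type_index <- function(params, codes) {
  idx <- match(codes, params$types$code)
  if (anyNA(idx)) {
    stop("atom type(s) not in ParameterSet: ",
         paste(unique(codes[is.na(idx)]), collapse = ", "))
  }
  idx
}

#' Look up 12-6 pair coefficients for two atom types
#' @param params a `ParameterSet`.
#' @param ti,tj atom type codes.
#' @return numeric `c(A, B)`.
#' @export
vdw_pair_coeffs <- function(params, ti, tj) {
  i <- type_index(params, ti); j <- type_index(params, tj)
  c(A = params$pairA[i, j], B = params$pairB[i, j])
}

#' Look up 12-10 hydrogen-bond pair coefficients (0 if pair not eligible)
#' @inheritParams vdw_pair_coeffs
#' @return numeric `c(C, D)`.
#' @export
hbond_pair_coeffs <- function(params, ti, tj) {
  i <- type_index(params, ti); j <- type_index(params, tj)
  c(C = params$hbC[i, j], D = params$hbD[i, j])
}

#' Write / read the per-type parameter table as self-describing text
#'
#' The table is whitespace-delimited with a `#`-comment header naming every
#' column and its units, so edited or refitted parameters can be dropped in
#' without touching code.
#'
#' @param params a `ParameterSet`.
#' @param path file path.
#' @export
write_parameter_table <- function(params, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    "# hingedock atom-type parameter table",
    "# code: atom type; rii: vdW sum-radius at minimum (A); eps: well depth (kcal/mol)",
    "# donor/acceptor: H-bond eligibility; S: solvation energy density (kcal/(mol.A^3))",
    "# V: fragmental volume (A^3); occmax: maximum occupancy (A^3)",
    sprintf("# weights: vdw=%g hbond=%g elec=%g tor=%g sol=%g sigma=%g",
            params$weights["vdw"], params$weights["hbond"],
            params$weights["elec"], params$weights["tor"],
            params$weights["sol"], params$sigma)), con)
  utils::write.table(params$types, con, quote = FALSE, row.names = FALSE)
}

#' @rdname write_parameter_table
#' @param base `ParameterSet` whose non-tabular constants are kept.
#' @return `read_parameter_table` returns a `ParameterSet` with the table
#'   replaced and pair matrices rebuilt.
#' @export
read_parameter_table <- function(path, base = default_parameters()) {
  tab <- utils::read.table(path, header = TRUE, comment.char = "#",
                           stringsAsFactors = FALSE)
  need <- c("code", "rii", "eps", "donor", "acceptor", "S", "V", "occmax")
  if (!all(need %in% names(tab))) {
    stop("parameter table must have columns: ", paste(need, collapse = ", "))
  }
  stopifnot(all(tab$V >= 0), all(tab$occmax > 0))
  rownames(tab) <- tab$code
  base$types <- tab
  rebuild_pair_tables(base)
}

#' @export
print.ParameterSet <- function(x, ...) {
  cat("ParameterSet:", nrow(x$types), "atom types\n")
  cat("  weights:", paste(sprintf("%s=%g", names(x$weights), x$weights),
                          collapse = " "), "\n")
  cat("  sigma:", x$sigma, "A; cutoff:", x$cutoff, "A\n")
  cat("  provenance:", x$provenance, "\n")
  invisible(x)
}
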