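# Per-element reference data. Masses are IUPAC standard (conventional) atomic
# weights rounded to 0.001 amu; radii in Angstrom (Bondi vdW, Pyykko covalent).

.ATOMIC_MASS <- c(
  H = 1.008, B = 10.811, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Na = 22.990, Mg = 24.305, Si = 28.085, P = 30.974, S = 32.060, Cl = 35.450,
  K = 39.098, Ca = 40.078, Zn = 65.380, Se = 78.971, Br = 79.904, I = 126.904
)

.VDW_RADIUS <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47, P = 1.80, S = 1.80,
  Cl = 1.75, Br = 1.85, I = 1.98, B = 1.92, Si = 2.10, Se = 1.90
)

.COV_RADIUS <- c(
  H = 0.31, B = 0.84, C = 0.76, N = 0.71, O = 0.66, F = 0.57, Si = 1.11,
  P = 1.07, S = 1.05, Cl = 1.02, Se = 1.20, Br = 1.20, I = 1.39
)

# Default valence used when inferring implicit hydrogen counts.
.DEFAULT_VALENCE <- c(
  H = 1, B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = 3, S = 2,
  Cl = 1, Br = 1, I = 1, Se = 2
)

# PEOE (Gasteiger-Marsili) orbital electronegativity coefficients a, b, c for
# chi(q) = a + b q + c q^2, in eV, keyed by element + hybridisation bucket.
.PEOE_PARAMS <- rbind(
  H      = c(7.17,  6.24, -0.56),
  C.sp3  = c(7.98,  9.18,  1.88),
  C.sp2  = c(8.79,  9.32,  1.51),
  C.sp   = c(10.39, 9.45,  0.73),
  N.sp3  = c(11.54, 10.82, 1.36),
  N.sp2  = c(12.87, 11.15, 0.85),
  N.sp   = c(15.68, 11.70, -0.27),
  O.sp3  = c(14.18, 12.92, 1.39),
  O.sp2  = c(17.07, 13.79, 0.47),
  F      = c(14.66, 13.85, 2.31),
  Cl     = c(11.00, 9.69,  1.35),
  Br     = c(10.08, 8.47,  1.16),
  I      = c(9.90,  7.96,  0.96),
  S.sp3  = c(10.14, 9.13,  1.38),
  S.sp2  = c(10.88, 9.49,  1.33),
  P.sp3  = c(8.90,  8.24,  0.96)
)
colnames(.PEOE_PARAMS) <- c("a", "b", "c")

element_mass <- function(element) {
  m <- .ATOMIC_MASS[element]
  if (anyNA(m)) {
    bad <- which(is.na(m))
    stop("unknown element(s) at atom index ", paste(bad, collapse = ", "),
         ": ", paste(unique(element[bad]), collapse = ", "))
  }
  unname(m)
}

#' Normalise an element symbol ("CL" -> "Cl")
#' @noRd
normalize_element <- function(x) {
  x <- trimws(x)
  paste0(toupper(substr(x, 1, 1)), tolower(substr(x, 2, nchar(x))))
}
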