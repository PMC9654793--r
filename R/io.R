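# Ligand library I/O. SDF V2000 records are parsed with ChemmineR; SMILES
# input is embedded in 3D (with explicit hydrogens) through the OpenBabel
# command-line tool, then parsed the same way.

#' Load a ligand library
#'
#' Reads a SMILES file (one record per line, optional whitespace-separated id
#' column) or an SDF V2000 file into a list of [molecule()] objects, in file
#' order. Invalid records are skipped and counted (reported via message and
#' the `skipped` attribute). SMILES input requires the `obabel` executable
#' for 3D embedding.
#'
#' @param path input file.
#' @param format `"smiles"`, `"sdf"`, or `"auto"` (inferred from extension).
#' @return list of `Molecule`s with attribute `skipped` (count of records
#'   that could not be parsed).
#' @export
load_library <- function(path, format = c("auto", "smiles", "sdf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read library file: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("smi", "smiles", "ism")) "smiles" else "sdf"
  }
  if (format == "smiles") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0) {
      out <- list(); attr(out, "skipped") <- 0L
      return(out)
    }
    if (Sys.which("obabel") == "") {
      stop("SMILES input needs the 'obabel' executable on PATH")
    }
    tmp_out <- tempfile(fileext = ".sdf")
    status <- suppressWarnings(system2(
      "obabel", c("-ismi", shQuote(path), "-osdf", "-O", shQuote(tmp_out),
                  "--gen3d", "-h"),
      stdout = FALSE, stderr = FALSE))
    if (status != 0 || !file.exists(tmp_out)) {
      stop("obabel failed to convert SMILES file: ", path)
    }
    mols <- read_sdf_molecules(tmp_out)
    skipped <- length(lines) - length(mols)
    if (skipped > 0) message(skipped, " SMILES record(s) skipped as unparsable")
    attr(mols, "skipped") <- as.integer(max(0L, skipped))
    return(mols)
  }
  mols <- read_sdf_molecules(path)
  n_rec <- sdf_record_count(path)
  skipped <- max(0L, n_rec - length(mols))
  if (skipped > 0) message(skipped, " SDF record(s) skipped as unparsable")
  if (length(mols) == 0) warning("no valid records in ", path)
  attr(mols, "skipped") <- as.integer(skipped)
  mols
}

#' @noRd
sdf_record_count <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) return(0L)
  n <- sum(grepl("^\\$\\$\\$\\$", lines))
  if (n == 0 && length(lines) > 3) n <- 1L   # single record without terminator
  n
}

#' @noRd
read_sdf_molecules <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || all(!nzchar(trimws(lines)))) return(list())
  sdfset <- tryCatch(
    suppressWarnings(ChemmineR::read.SDFset(path, skipErrors = TRUE)),
    error = function(e) NULL)
  if (is.null(sdfset)) return(list())
  ok <- tryCatch(ChemmineR::validSDF(sdfset), error = function(e) rep(FALSE, length(sdfset)))
  out <- list()
  for (i in which(ok)) {
    m <- tryCatch(sdf_to_molecule(sdfset[[i]]), error = function(e) NULL)
    if (!is.null(m)) out[[length(out) + 1L]] <- m
  }
  out
}

#' @noRd
sdf_to_molecule <- function(sdf) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  el <- sub("_.*$", "", rownames(ab))
  atoms <- data.frame(element = normalize_element(el),
                      x = ab[, 1], y = ab[, 2], z = ab[, 3])
  bonds <- if (is.null(bb) || nrow(bb) == 0) NULL else
    data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
               order = as.integer(bb[, 3]))
  nm <- unname(ChemmineR::sdfid(sdf))
  if (is.null(nm) || is.na(nm) || !nzchar(nm)) nm <- "mol"
  molecule(atoms, bonds, name = nm)
}

#' Write molecules (or posed conformers) to an SDF file
#'
#' @param mols list of `Molecule`s, or a single `Molecule`.
#' @param path output path.
#' @param energies optional numeric vector written as an `energy` data field.
#' @export
write_sdf <- function(mols, path, energies = NULL) {
  if (inherits(mols, "Molecule")) mols <- list(mols)
  con <- file(path, "w"); on.exit(close(con))
  for (k in seq_along(mols)) {
    m <- mols[[k]]
    na <- nrow(m$atoms); nb <- nrow(m$bonds)
    writeLines(c(m$name, "  hingedock", ""), con)
    writeLines(sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb), con)
    for (i in seq_len(na)) {
      writeLines(sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                         m$atoms$x[i], m$atoms$y[i], m$atoms$z[i], m$atoms$element[i]), con)
    }
    for (b in seq_len(nb)) {
      writeLines(sprintf("%3d%3d%3d  0  0  0  0", m$bonds$i[b], m$bonds$j[b],
                         min(m$bonds$order[b], 4L)), con)
    }
    writeLines("M  END", con)
    if (!is.null(energies) && length(energies) >= k && is.finite(energies[k])) {
      writeLines(c("> <energy>", sprintf("%.4f", energies[k]), ""), con)
    }
    writeLines("$$$$", con)
  }
  invisible(path)
}

#' Write a receptor model to PDB, with per-residue protonation decisions
#' recorded in REMARK lines
#'
#' @param rec a `Receptor`.
#' @param path output path.
#' @export
write_receptor_pdb <- function(rec, path) {
  tmp <- tempfile(fileext = ".pdb")
  a <- rec$atoms
  bio3d::write.pdb(file = tmp, xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = rep("ATOM", nrow(a)), resno = a$resno, resid = a$resname,
                   chain = a$chain, elety = a$name, elesy = a$element)
  remarks <- "REMARK   6 hingedock protonated receptor model"
  if (!is.null(rec$protonation) && nrow(rec$protonation) > 0) {
    remarks <- c(remarks, sprintf(
      "REMARK   6 %s %s%d -> %s%s (%s)",
      rec$protonation$resname, rec$protonation$chain, rec$protonation$resno,
      rec$protonation$state,
      ifelse(nzchar(rec$protonation$tautomer), paste0("/", rec$protonation$tautomer), ""),
      rec$protonation$reason))
  }
  writeLines(c(remarks, readLines(tmp, warn = FALSE)), path)
  invisible(path)
}
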