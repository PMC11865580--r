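# Structure reading, annotation and selection. Parsing is delegated to
# bio3d; this layer normalizes the atom table to the package's conventions
# (altloc resolution, water/hetero stripping, element-level polarity and
# van der Waals annotation).

# Element-level van der Waals radii (Angstrom), Chothia-style values as used
# by NACCESS-type SASA programs. Pinned here because SASA magnitudes depend
# on the radii set; override per call via `vdw_radii`.
.vdw_default <- c(
  C = 1.87, N = 1.65, O = 1.40, S = 1.85, P = 1.90,
  H = 1.00, D = 1.00, SE = 1.90, F = 1.47, CL = 1.75,
  BR = 1.85, I = 1.98
)
.vdw_fallback <- 1.80

#' Default van der Waals radii table
#'
#' Element-level Chothia-style radii (Angstrom) used for SASA calculations.
#' Elements absent from the table fall back to 1.80 Angstrom.
#'
#' @return Named numeric vector of radii by element symbol.
#' @export
vdw_radii_default <- function() .vdw_default

.element_from_name <- function(name) {
  two <- c("SE", "FE", "ZN", "MG", "CL", "BR", "NA", "MN", "CU")
  vapply(name, function(nm) {
    nm <- gsub("[0-9']", "", toupper(trimws(nm)))
    if (nzchar(nm) && substr(nm, 1, 2) %in% two) return(substr(nm, 1, 2))
    if (nzchar(nm)) substr(nm, 1, 1) else "C"
  }, character(1), USE.NAMES = FALSE)
}

#' Construct a structure model from an atom table
#'
#' Low-level constructor used by [read_structure()] and by the synthetic
#' fixture generators. The atom table must contain `serial`, `name`,
#' `element`, `resid`, `resno`, `chain`, `x`, `y`, `z` (and optionally
#' `occ`). Heavy/polar flags and van der Waals radii are derived from the
#' element column: polar means element N or O; heavy means element other
#' than H or D.
#'
#' @param atoms data.frame of atom records.
#' @param source_id identifier string recorded on the model.
#' @param vdw_radii optional named numeric vector overriding the default
#'   element radii table.
#' @return An object of class `structure_model`.
#' @export
new_structure_model <- function(atoms, source_id = "model", vdw_radii = NULL) {
  need <- c("serial", "name", "element", "resid", "resno", "chain",
            "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stop("atom table lacks column(s): ", paste(miss, collapse = ", "))
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  if (is.null(atoms$occ)) atoms$occ <- 1
  bad <- !is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)
  if (any(bad))
    stop("non-finite coordinates for atom serial(s): ",
         paste(atoms$serial[bad], collapse = ", "))
  atoms$element <- toupper(atoms$element)
  atoms$is_heavy <- !(atoms$element %in% c("H", "D"))
  atoms$is_polar <- atoms$element %in% c("N", "O")
  radii <- .vdw_default
  if (!is.null(vdw_radii)) radii[names(vdw_radii)] <- vdw_radii
  atoms$vdw <- unname(radii[atoms$element])
  atoms$vdw[is.na(atoms$vdw)] <- .vdw_fallback
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, source_id = source_id),
            class = "structure_model")
}

#' Read a macromolecular structure
#'
#' Reads a PDB or mmCIF file (via bio3d), keeping the first model only.
#' Alternate locations are resolved to the highest-occupancy conformer
#' (ties: first encountered). Waters and non-polymer heteroatoms are
#' excluded by default. Hydrogens are retained but flagged `is_heavy =
#' FALSE`, so downstream SASA and convexity operations ignore them.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"pdb"` or `"cif"`.
#' @param keep_hetero keep non-water HETATM records.
#' @param keep_water keep crystallographic waters.
#' @param vdw_radii optional named radii override (see
#'   [vdw_radii_default()]).
#' @return A `structure_model`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif"),
                           keep_hetero = FALSE, keep_water = FALSE,
                           vdw_radii = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "cif" else "pdb"
  }
  parsed <- tryCatch(
    if (format == "cif") bio3d::read.cif(path, verbose = FALSE)
    else bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                         verbose = FALSE),
    error = function(e)
      stop("failed to parse ", path, " as ", format, ": ",
           conditionMessage(e), call. = FALSE))
  at <- parsed$atom
  if (is.null(at) || nrow(at) == 0) stop("no atoms parsed from ", path)

  water <- at$resid %in% c("HOH", "WAT", "DOD", "H2O")
  keep <- rep(TRUE, nrow(at))
  if (!keep_water) keep <- keep & !water
  if (!keep_hetero) keep <- keep & (at$type == "ATOM" | (keep_water & water))
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0) stop("no atoms retained from ", path)

  # altloc: keep highest occupancy per (chain, resno, insert, atom name)
  alt <- at$alt
  has_alt <- !is.na(alt) & alt != "" & alt != " "
  if (any(has_alt)) {
    key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
    occ <- ifelse(is.na(at$o), 1, at$o)
    ord <- order(key, -occ, seq_len(nrow(at)))
    keep2 <- rep(TRUE, nrow(at))
    keep2[ord[duplicated(key[ord])]] <- FALSE
    at <- at[keep2, , drop = FALSE]
  }

  elem <- at$elesy
  if (is.null(elem)) elem <- rep(NA_character_, nrow(at))
  blank <- is.na(elem) | !nzchar(trimws(elem))
  elem[blank] <- .element_from_name(at$elety[blank])
  chain <- ifelse(is.na(at$chain) | at$chain == "", "A", at$chain)

  model <- new_structure_model(
    data.frame(serial = at$eleno, name = trimws(at$elety),
               element = trimws(elem), resid = at$resid, resno = at$resno,
               chain = chain, x = at$x, y = at$y, z = at$z,
               occ = ifelse(is.na(at$o), 1, at$o),
               stringsAsFactors = FALSE),
    source_id = basename(path), vdw_radii = vdw_radii)
  if (!any(model$atoms$is_heavy))
    stop("structure ", path, " contains no heavy atoms")
  model
}

#' Select atoms from a structure model
#'
#' Order-preserving subsetting by chain, heaviness and atom name. The name
#' filter is applied after the chain filter.
#'
#' @param model a `structure_model`.
#' @param chains chain identifiers to keep (`NULL` = all).
#' @param heavy_only drop hydrogens/deuteriums.
#' @param names optional atom-name set (e.g. `"CA"`).
#' @return data.frame of atom records (subset of `model$atoms`).
#' @export
select_atoms <- function(model, chains = NULL, heavy_only = FALSE,
                         names = NULL) {
  stopifnot(inherits(model, "structure_model"))
  at <- model$atoms
  if (!is.null(chains)) {
    avail <- unique(at$chain)
    unknown <- setdiff(chains, avail)
    if (length(unknown))
      stop("unknown chain(s) ", paste(unknown, collapse = ", "),
           "; available: ", paste(avail, collapse = ", "))
    at <- at[at$chain %in% chains, , drop = FALSE]
  }
  if (heavy_only) at <- at[at$is_heavy, , drop = FALSE]
  if (!is.null(names)) at <- at[at$name %in% names, , drop = FALSE]
  at
}

#' List chains of a model
#' @param model a `structure_model`.
#' @return character vector of chain ids in order of first appearance.
#' @export
model_chains <- function(model) unique(model$atoms$chain)

# Subset a model to a chain set, preserving class and annotations.
subset_model <- function(model, chains) {
  at <- select_atoms(model, chains = chains)
  out <- model
  out$atoms <- at
  rownames(out$atoms) <- NULL
  out
}

#' Write a structure model as PDB
#'
#' Fixed-width PDB output via bio3d; used for fixtures and aligned models.
#'
#' @param model a `structure_model`.
#' @param path output file.
#' @param b optional per-atom B-factor vector (e.g. a conservation profile
#'   mapped onto residues).
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path, b = NULL) {
  stopifnot(inherits(model, "structure_model"))
  at <- model$atoms
  if (is.null(b)) b <- rep(0, nrow(at))
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
                   resno = at$resno, resid = at$resid, eleno = at$serial,
                   elety = at$name, chain = at$chain, o = at$occ, b = b,
                   elesy = at$element)
  invisible(path)
}

#' @export
print.structure_model <- function(x, ...) {
  at <- x$atoms
  cat("structure_model:", x$source_id, "\n")
  cat(" ", nrow(at), "atoms (", sum(at$is_heavy), "heavy ) in",
      length(unique(at$chain)), "chain(s):",
      paste(unique(at$chain), collapse = " "), "\n")
  invisible(x)
}

# Coordinate matrix helper
atom_xyz <- function(atoms) as.matrix(atoms[, c("x", "y", "z"), drop = FALSE])
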