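# Solvent-accessible surface area and dSASA-defined interfaces.
#
# SASA uses Shrake-Rupley sampling with a deterministic golden-spiral point
# set shared by every call. With a fixed point set, burial is monotone in
# the atom set: computing a partner alone (apo) and inside the complex
# (holo) with identical sampling guarantees dSASA = apo - holo >= 0 for
# every atom, which the interface definition relies on.

# Canonical molecular frame: center on the centroid and rotate onto the
# principal axes, with each axis oriented by the sign of its third moment
# (deterministic, and equivariant under rigid motions of the input, which
# makes SASA rigid-motion invariant to numerical precision). Clouds with
# vanishing third moments keep the eigenvector orientation as computed:
# still deterministic for identical input.
.canonical_frame <- function(xyz) {
  x0 <- sweep(xyz, 2, colMeans(xyz))
  if (nrow(x0) < 2) return(x0)
  e <- eigen(crossprod(x0), symmetric = TRUE)
  V <- e$vectors
  for (k in 1:3) {
    m3 <- sum((x0 %*% V[, k])^3)
    if (m3 < 0) V[, k] <- -V[, k]
  }
  if (det(V) < 0) V[, 3] <- -V[, 3]
  x0 %*% V
}

#' Per-atom solvent-accessible surface area
#'
#' Shrake-Rupley SASA over the heavy atoms of a model. Hydrogens are
#' ignored for occlusion and assigned area 0. Sampling uses a
#' golden-section spiral applied in a canonical molecular frame
#' (principal axes), so results are deterministic (no seed) and invariant
#' under rigid motions of the input.
#'
#' @param model a `structure_model`.
#' @param probe_radius probe sphere radius in Angstrom (water: 1.4).
#' @param n_sphere_points number of sampling points per atom (>= 60).
#' @param frame `"canonical"` (default) evaluates in the principal-axis
#'   frame; `"fixed"` uses the coordinates as given. [interfacial_atoms()]
#'   uses a single fixed frame for apo and holo so that per-atom burial is
#'   exactly monotone (dSASA >= 0).
#' @return A numeric vector of class `sasa_map`, aligned to
#'   `model$atoms`, with attributes `probe_radius` and `n_sphere_points`.
#' @export
compute_sasa <- function(model, probe_radius = 1.4, n_sphere_points = 960,
                         frame = c("canonical", "fixed")) {
  frame <- match.arg(frame)
  stopifnot(inherits(model, "structure_model"))
  if (probe_radius <= 0) stop("probe_radius must be > 0")
  if (n_sphere_points < 60) stop("n_sphere_points must be >= 60")
  at <- model$atoms
  heavy <- which(at$is_heavy)
  if (!length(heavy)) stop("model has no heavy atoms")
  xyz <- atom_xyz(at[heavy, ])
  bad <- which(!is.finite(rowSums(xyz)))
  if (length(bad))
    stop("non-finite coordinates for atom serial(s): ",
         paste(at$serial[heavy[bad]], collapse = ", "))
  if (frame == "canonical") xyz <- .canonical_frame(xyz)
  area <- numeric(nrow(at))
  area[heavy] <- .sasa_kernel(xyz, at$vdw[heavy], probe_radius,
                              as.integer(n_sphere_points))
  structure(area, probe_radius = probe_radius,
            n_sphere_points = as.integer(n_sphere_points),
            class = "sasa_map")
}

.model_signature <- function(model, chains) {
  at <- select_atoms(model, chains = chains)
  paste(model$source_id, nrow(at), sum(at$is_heavy), sep = "|")
}

#' Interfacial atoms by apo/holo dSASA
#'
#' For each partner, SASA is computed on the isolated partner (apo, atoms
#' extracted from the complex coordinates) and in the two-partner complex
#' (holo) with identical sampling. Heavy atoms whose SASA difference
#' (dSASA = apo - holo) is at least `dsasa_threshold` (default 0.5
#' Angstrom^2) are interfacial.
#'
#' @param model a `structure_model` containing both partners.
#' @param partner_a,partner_b disjoint, non-empty chain sets.
#' @param dsasa_threshold minimum per-atom dSASA in Angstrom^2.
#' @param probe_radius,n_sphere_points passed to [compute_sasa()].
#' @return An `interface_partition`: per-partner data.frames of
#'   interfacial atom records with their dSASA.
#' @export
interfacial_atoms <- function(model, partner_a, partner_b,
                              dsasa_threshold = 0.5, probe_radius = 1.4,
                              n_sphere_points = 960) {
  stopifnot(inherits(model, "structure_model"))
  if (!length(partner_a) || !length(partner_b))
    stop("partner chain sets must be non-empty")
  if (length(intersect(partner_a, partner_b)))
    stop("partner chain sets overlap: ",
         paste(intersect(partner_a, partner_b), collapse = ", "))
  holo_model <- subset_model(model, c(partner_a, partner_b))
  at <- holo_model$atoms
  heavy <- which(at$is_heavy)
  # one canonical frame, derived from the complex, shared by the apo and
  # holo evaluations (coordinates reported in the partition stay in the
  # input frame): with an identical sampling point set, removing the
  # partner can only expose surface, so dSASA = apo - holo >= 0 exactly
  xyzc <- .canonical_frame(atom_xyz(at[heavy, ]))
  np <- as.integer(n_sphere_points)
  holo_area <- numeric(nrow(at))
  holo_area[heavy] <- .sasa_kernel(xyzc, at$vdw[heavy], probe_radius, np)

  one_side <- function(mask) {
    sub_heavy <- heavy[mask[heavy]]
    apo_area <- numeric(length(sub_heavy))
    if (length(sub_heavy))
      apo_area <- .sasa_kernel(xyzc[mask[heavy], , drop = FALSE],
                               at$vdw[sub_heavy], probe_radius, np)
    ds <- apo_area - holo_area[sub_heavy]
    hit <- which(ds >= dsasa_threshold)
    out <- at[sub_heavy[hit], , drop = FALSE]
    out$dsasa <- ds[hit]
    rownames(out) <- NULL
    out
  }

  in_a <- at$chain %in% partner_a
  structure(list(a = one_side(in_a), b = one_side(!in_a),
                 partner_a = partner_a, partner_b = partner_b,
                 dsasa_threshold = dsasa_threshold,
                 probe_radius = probe_radius,
                 n_sphere_points = as.integer(n_sphere_points),
                 signature = .model_signature(model,
                                              c(partner_a, partner_b))),
            class = "interface_partition")
}

#' @export
print.interface_partition <- function(x, ...) {
  cat("interface_partition (dSASA >=", x$dsasa_threshold, "A^2)\n")
  cat("  partner A [", paste(x$partner_a, collapse = ","), "]: ",
      nrow(x$a), " interfacial atoms\n", sep = "")
  cat("  partner B [", paste(x$partner_b, collapse = ","), "]: ",
      nrow(x$b), " interfacial atoms\n", sep = "")
  invisible(x)
}

#' Buried-area split of an interface
#'
#' Sums interfacial dSASA into polar (elements N, O) and apolar (all other
#' heavy elements) components, per partner and summed over both partners.
#'
#' @param partition an `interface_partition` from [interfacial_atoms()].
#' @param model the `structure_model` the partition was produced from.
#' @return A data.frame of class `buried_area` with rows `partner_a`,
#'   `partner_b`, `total` and columns `polar`, `apolar`, `total`
#'   (Angstrom^2).
#' @export
buried_area <- function(partition, model) {
  stopifnot(inherits(partition, "interface_partition"),
            inherits(model, "structure_model"))
  sig <- tryCatch(
    .model_signature(model, c(partition$partner_a, partition$partner_b)),
    error = function(e) "<chains absent>")
  if (!identical(sig, partition$signature))
    stop("partition does not match model (signature mismatch: ",
         partition$signature, " vs ", sig, ")")
  split2 <- function(df) {
    c(polar = sum(df$dsasa[df$is_polar]),
      apolar = sum(df$dsasa[!df$is_polar]))
  }
  pa <- split2(partition$a); pb <- split2(partition$b)
  out <- data.frame(polar = c(pa["polar"], pb["polar"],
                              pa["polar"] + pb["polar"]),
                    apolar = c(pa["apolar"], pb["apolar"],
                               pa["apolar"] + pb["apolar"]))
  out$total <- out$polar + out$apolar
  rownames(out) <- c("partner_a", "partner_b", "total")
  class(out) <- c("buried_area", "data.frame")
  out
}

#' Residue-level view of an interface
#'
#' Convenience reporting view: a residue is interfacial iff it has at least
#' one interfacial atom.
#'
#' @param partition an `interface_partition`.
#' @return data.frame of interfacial residues (partner, chain, resno,
#'   resid, n_atoms, dsasa sum).
#' @export
interface_residues <- function(partition) {
  stopifnot(inherits(partition, "interface_partition"))
  per <- function(df, label) {
    if (!nrow(df))
      return(data.frame(partner = character(), chain = character(),
                        resno = integer(), resid = character(),
                        n_atoms = integer(), dsasa = numeric()))
    agg <- aggregate(df$dsasa,
                     by = list(chain = df$chain, resno = df$resno,
                               resid = df$resid), FUN = sum)
    cnt <- aggregate(df$dsasa,
                     by = list(chain = df$chain, resno = df$resno,
                               resid = df$resid), FUN = length)
    out <- data.frame(partner = label, chain = agg$chain, resno = agg$resno,
                      resid = agg$resid, n_atoms = cnt$x, dsasa = agg$x)
    out[order(out$chain, out$resno), ]
  }
  out <- rbind(per(partition$a, "a"), per(partition$b, "b"))
  rownames(out) <- NULL
  out
}

#' Write per-atom interface table as TSV
#'
#' One row per interfacial atom: partner, chain, residue number, residue
#' name, atom name, element, dSASA.
#'
#' @param partition an `interface_partition`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_interface_tsv <- function(partition, path) {
  stopifnot(inherits(partition, "interface_partition"))
  fmt <- function(df, label)
    if (nrow(df)) data.frame(partner = label,
                             df[, c("chain", "resno", "resid", "name",
                                    "element", "dsasa")])
    else NULL
  out <- rbind(fmt(partition$a, "a"), fmt(partition$b, "b"))
  if (is.null(out))
    out <- data.frame(partner = character(), chain = character(),
                      resno = integer(), resid = character(),
                      name = character(), element = character(),
                      dsasa = numeric())
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
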