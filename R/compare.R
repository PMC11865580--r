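# Rigid-body superposition (Kabsch), C-alpha RMSD between models or
# crystal structures, and pairwise sequence identity.

#' Kabsch least-squares superposition
#'
#' Optimal proper rotation + translation mapping `coords_a` onto
#' `coords_b` (SVD of the cross-covariance; reflections are excluded by
#' a determinant sign correction, preserving chirality). RMSD is
#' computed after applying the transform.
#'
#' @param coords_a,coords_b paired n x 3 coordinate matrices, n >= 3,
#'   not all collinear.
#' @return A `superposition`: `rotation` (3 x 3, det +1), `translation`
#'   (3-vector; transform is `x %*% t(rotation) + translation`), `rmsd`
#'   (Angstrom), `n_atoms_used`, `pairing`.
#' @export
kabsch_superpose <- function(coords_a, coords_b) {
  a <- .as_points(coords_a); b <- .as_points(coords_b)
  if (nrow(a) != nrow(b))
    stop("pairing error: ", nrow(a), " vs ", nrow(b), " atoms")
  n <- nrow(a)
  if (n < 3) stop("need >= 3 paired atoms, got ", n)
  ca <- colMeans(a); cb <- colMeans(b)
  a0 <- sweep(a, 2, ca); b0 <- sweep(b, 2, cb)
  H <- t(a0) %*% b0
  s <- svd(H)
  span_a <- svd(a0)$d
  if (span_a[2] < 1e-8 * max(span_a[1], 1))
    stop("degenerate geometry: points are collinear")
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  rot <- a0 %*% t(R)
  rmsd <- sqrt(mean(rowSums((rot - b0)^2)))
  structure(list(rotation = R, translation = as.numeric(cb - R %*% ca),
                 rmsd = rmsd, n_atoms_used = n, pairing = NULL),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat("superposition: rmsd", format(x$rmsd, digits = 4), "A over",
      x$n_atoms_used, "atoms\n")
  invisible(x)
}

.three_to_one <- function(resid) {
  out <- suppressWarnings(bio3d::aa321(resid))
  out[is.na(out) | !out %in% c(aa_alphabet(), "X")] <- "X"
  out
}

.ca_table <- function(model, chain) {
  at <- select_atoms(model, chains = chain, heavy_only = TRUE,
                     names = "CA")
  at <- at[order(match(at$chain, chain %||% unique(at$chain)),
                 at$resno), , drop = FALSE]
  at[!duplicated(paste(at$chain, at$resno)), , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Global alignment (match 1 / mismatch 0 / gap -1) of two residue strings;
# returns the aligned index pairs (both non-gap columns).
.align_pairs <- function(seq_a, seq_b) {
  alpha <- c(aa_alphabet(), "X")
  sm <- matrix(0, length(alpha), length(alpha),
               dimnames = list(alpha, alpha))
  diag(sm) <- 1
  sm["X", "X"] <- 0  # X never counts as a match
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(paste(seq_a, collapse = "")),
    Biostrings::AAString(paste(seq_b, collapse = "")),
    substitutionMatrix = sm, gapOpening = 0, gapExtension = 1,
    type = "global")
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ia <- ib <- 0L
  pairs <- matrix(0L, 0, 2)
  cols <- length(pa)
  out <- matrix(NA_integer_, cols, 2)
  k <- 0L
  for (i in seq_len(cols)) {
    ga <- pa[i] == "-"; gb <- pb[i] == "-"
    if (!ga) ia <- ia + 1L
    if (!gb) ib <- ib + 1L
    if (!ga && !gb) { k <- k + 1L; out[k, ] <- c(ia, ib) }
  }
  list(pairs = out[seq_len(k), , drop = FALSE], n_columns = cols,
       aligned_a = pa, aligned_b = pb)
}

#' C-alpha RMSD between two models
#'
#' Pairs C-alpha atoms either by global sequence alignment (default) or
#' by common residue numbers, then applies [kabsch_superpose()].
#'
#' @param model_a,model_b `structure_model`s.
#' @param chain_a,chain_b chains to compare (`NULL` = all chains of the
#'   model, concatenated in order).
#' @param pairing `"alignment"` (global sequence alignment, matched
#'   positions) or `"resno"` (common residue numbers).
#' @return A `superposition` with `pairing` describing the matched
#'   residues.
#' @export
ca_rmsd <- function(model_a, model_b, chain_a = NULL, chain_b = NULL,
                    pairing = c("alignment", "resno")) {
  pairing <- match.arg(pairing)
  ta <- .ca_table(model_a, chain_a)
  tb <- .ca_table(model_b, chain_b)
  if (!nrow(ta) || !nrow(tb)) stop("no CA atoms to pair")
  if (pairing == "resno") {
    common <- intersect(ta$resno, tb$resno)
    if (length(common) < 3)
      stop("pairing error: only ", length(common), " common residues")
    ia <- match(common, ta$resno); ib <- match(common, tb$resno)
  } else {
    sa <- .three_to_one(ta$resid); sb <- .three_to_one(tb$resid)
    al <- .align_pairs(sa, sb)
    if (nrow(al$pairs) < 3)
      stop("pairing error: alignment matched only ", nrow(al$pairs),
           " positions")
    ia <- al$pairs[, 1]; ib <- al$pairs[, 2]
  }
  sup <- kabsch_superpose(atom_xyz(ta[ia, ]), atom_xyz(tb[ib, ]))
  sup$pairing <- data.frame(resno_a = ta$resno[ia], chain_a = ta$chain[ia],
                            resno_b = tb$resno[ib], chain_b = tb$chain[ib])
  sup
}

#' Pairwise sequence identity
#'
#' Ungapped mode requires equal lengths: identity = matches / length x
#' 100. Global mode aligns first (match 1 / mismatch 0 / gap -1) and
#' divides matches by the number of alignment columns. `X` is tolerated
#' but never counts as a match. Reported to 2 decimals.
#'
#' @param seq_a,seq_b amino-acid strings.
#' @param mode `"ungapped"` (equal length) or `"global"`.
#' @return identity percentage (numeric).
#' @export
sequence_identity <- function(seq_a, seq_b,
                              mode = c("ungapped", "global")) {
  mode <- match.arg(mode)
  clean <- function(s) {
    v <- strsplit(toupper(s), "")[[1]]
    if (!length(v)) stop("empty sequence")
    bad <- setdiff(v, c(aa_alphabet(), "X"))
    if (length(bad))
      stop("invalid residue symbol(s): ", paste(unique(bad),
                                                collapse = ", "))
    v
  }
  a <- clean(seq_a); b <- clean(seq_b)
  if (mode == "ungapped") {
    if (length(a) != length(b))
      stop("ungapped mode requires equal lengths (", length(a), " vs ",
           length(b), ")")
    matches <- sum(a == b & a != "X")
    return(round(matches / length(a) * 100, 2))
  }
  al <- .align_pairs(a, b)
  matches <- sum(al$aligned_a == al$aligned_b & al$aligned_a != "-" &
                   al$aligned_a != "X")
  round(matches / al$n_columns * 100, 2)
}
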