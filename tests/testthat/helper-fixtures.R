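# Shared fixture builders. Everything is generated in code; the only
# hand-written artifact is a tiny PDB text fixture that serves as its own
# specification.

# Minimal structure model from a coordinate matrix of pseudo-atoms.
mk_model <- function(xyz, chain = "A", element = "C", name = "CA",
                     resid = "ALA", resno = NULL, vdw = NULL,
                     source_id = "fixture") {
  n <- nrow(xyz)
  if (is.null(resno)) resno <- seq_len(n)
  new_structure_model(
    data.frame(serial = seq_len(n), name = name, element = element,
               resid = resid, resno = resno, chain = chain,
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
               stringsAsFactors = FALSE),
    source_id = source_id, vdw_radii = vdw)
}

# Hand-written 3-atom glycine PDB (N, CA, C), optionally with a hydrogen.
gly_pdb_file <- function(with_hydrogen = FALSE) {
  lines <- c(
    "ATOM      1  N   GLY A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  GLY A   1      11.639   6.071  -5.147  1.00  0.00           C",
    "ATOM      3  C   GLY A   1      10.729   6.768  -4.123  1.00  0.00           C")
  if (with_hydrogen)
    lines <- c(lines,
    "ATOM      4  H   GLY A   1      10.551   5.641  -6.669  1.00  0.00           H")
  path <- tempfile(fileext = ".pdb")
  writeLines(c(lines, "END"), path)
  path
}

# Points on (or near) a sphere: n points on the full sphere of radius r,
# with optional uniform radial noise and displaced outliers.
sphere_cloud <- function(n, r = 10, center = c(0, 0, 0), noise = 0,
                         n_outliers = 0, outlier_shift = 5,
                         cap_angle = NULL) {
  frac <- if (is.null(cap_angle)) 1 else
    (1 - cos(cap_angle * pi / 180)) / 2
  u <- matrix(rnorm(3 * ceiling(4 * n / frac)), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  if (!is.null(cap_angle)) u <- u[u[, 3] > cos(cap_angle * pi / 180), , drop = FALSE]
  u <- u[seq_len(n), , drop = FALSE]
  rad <- r + runif(n, -noise, noise)
  pts <- u * rad
  out <- NULL
  if (n_outliers > 0) {
    v <- matrix(rnorm(3 * n_outliers), ncol = 3)
    v <- v / sqrt(rowSums(v^2))
    out <- v * (r + outlier_shift + runif(n_outliers, 0, 2))
  }
  sweep(rbind(pts, out), 2, center, `+`)
}

# Independent brute-force sphere RANSAC: exhaustive enumeration of every
# 4-point subset with the same ranking rule (most inliers, then smaller
# inlier RMSE, then earlier subset). Returns the winning candidate's
# inlier index set.
brute_force_sphere_inliers <- function(pts, threshold) {
  n <- nrow(pts)
  combs <- utils::combn(n, 4)
  best <- NULL
  for (j in seq_len(ncol(combs))) {
    idx <- combs[, j]
    p <- pts[idx, , drop = FALSE]
    # exact sphere through 4 points via the linear system
    A <- 2 * (p[2:4, , drop = FALSE] - matrix(p[1, ], 3, 3, byrow = TRUE))
    b <- rowSums(p[2:4, , drop = FALSE]^2) - sum(p[1, ]^2)
    if (abs(det(A)) < 1e-8 * max(abs(A))^3) next
    ctr <- solve(A, b)
    r <- sqrt(sum((p[1, ] - ctr)^2))
    resid <- sqrt(rowSums(sweep(pts, 2, ctr)^2)) - r
    inl <- which(abs(resid) <= threshold)
    if (length(inl) < 4) next
    rmse <- sqrt(mean(resid[inl]^2))
    if (is.null(best) || length(inl) > length(best$inl) ||
        (length(inl) == length(best$inl) && rmse < best$rmse)) {
      best <- list(inl = inl, rmse = rmse, center = ctr, radius = r)
    }
  }
  best
}

# Toy bundle with a varied (non-homopolymer) sequence so that sequence
# alignments are unambiguous.
varied_bundle <- function(...) {
  tb <- make_toy_bundle(...)
  resnos <- sort(unique(tb$atoms$resno))
  codes <- bio3d::aa123(rep(aa_alphabet(), length.out = length(resnos)))
  tb$atoms$resid <- codes[match(tb$atoms$resno, resnos)]
  tb
}

# Rotation matrix about the z axis
rot_z <- function(theta)
  matrix(c(cos(theta), sin(theta), 0,
           -sin(theta), cos(theta), 0,
           0, 0, 1), 3, 3)

# Generic rotation from Euler-like composition (used by grid oracles)
rot_xyz <- function(a, b, c) {
  Rx <- matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
  Ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3, 3)
  Rx %*% Ry %*% rot_z(c)
}

# SSM count fixture with equal pool totals: a single enriched cell.
equal_total_counts <- function(L = 2, hot = c(1, 1), sel_hot = 20,
                               ref_hot = 10, filler = 30) {
  sel <- ref <- matrix(0L, L, 20)
  sel[hot[1], hot[2]] <- sel_hot
  ref[hot[1], hot[2]] <- ref_hot
  # balance totals in a far-away cell
  sel[L, 20] <- filler
  ref[L, 20] <- filler + (sel_hot - ref_hot)
  list(selected = sel, reference = ref)
}
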