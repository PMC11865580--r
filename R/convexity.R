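# Signed interface convexity: RANSAC sphere fits on interfacial atom
# coordinates. Convexity is the reciprocal of the fitted sphere radius,
# signed negative for concave (pocket-like) patches by an inner-product
# test on the interfacial centroid, the molecule centroid and the fitted
# sphere center.

new_sphere_fit <- function(center, radius, inlier_indices, inlier_rmse,
                           n_iterations_used, seed = NA_integer_,
                           method = "lsq") {
  structure(list(center = as.numeric(center), radius = as.numeric(radius),
                 inlier_indices = as.integer(inlier_indices),
                 inlier_rmse = as.numeric(inlier_rmse),
                 n_iterations_used = as.integer(n_iterations_used),
                 seed = seed, method = method),
            class = "sphere_fit")
}

#' @export
print.sphere_fit <- function(x, ...) {
  cat("sphere_fit (", x$method, "): radius ",
      format(x$radius, digits = 6), " A, center (",
      paste(format(x$center, digits = 5), collapse = ", "), "), ",
      length(x$inlier_indices), " inliers, rmse ",
      format(x$inlier_rmse, digits = 4), "\n", sep = "")
  invisible(x)
}

.as_points <- function(points) {
  pts <- as.matrix(points)
  if (ncol(pts) != 3) stop("points must be an n x 3 matrix")
  storage.mode(pts) <- "double"
  if (any(!is.finite(pts))) stop("points contain non-finite coordinates")
  pts
}

#' Algebraic least-squares sphere fit
#'
#' Closed-form fit of a sphere to all points by linearizing
#' \eqn{\|x\|^2 = 2 c \cdot x + (r^2 - \|c\|^2)} into an ordinary
#' least-squares system. All points are treated as inliers; no threshold
#' is applied. Serves as the refinement step of [fit_sphere_ransac()] and
#' as a brute-force oracle.
#'
#' @param points n x 3 coordinate matrix, n >= 4, not all coplanar.
#' @return A `sphere_fit`.
#' @export
fit_sphere_lsq <- function(points) {
  pts <- .as_points(points)
  n <- nrow(pts)
  if (n < 4) stop("degenerate geometry: need >= 4 points, got ", n)
  A <- cbind(2 * pts, 1)
  b <- rowSums(pts^2)
  qrA <- qr(A)
  if (qrA$rank < 4)
    stop("degenerate geometry: points are coplanar or collinear ",
         "(rank ", qrA$rank, " < 4)")
  beta <- qr.coef(qrA, b)
  center <- beta[1:3]
  r2 <- beta[4] + sum(center^2)
  if (!is.finite(r2) || r2 <= 0)
    stop("degenerate geometry: non-positive squared radius")
  radius <- sqrt(r2)
  resid <- sqrt(rowSums(sweep(pts, 2, center)^2)) - radius
  new_sphere_fit(center, radius, seq_len(n), sqrt(mean(resid^2)),
                 n_iterations_used = 0L, method = "lsq")
}

#' RANSAC sphere fit
#'
#' Repeatedly samples 4 points uniformly without replacement, solves the
#' exact 4-point sphere, and counts inliers with \eqn{|dist - r| \le}
#' `threshold`. The candidate with the most inliers wins (ties: smaller
#' inlier RMSE, then earlier iteration). The winner is refit by
#' [fit_sphere_lsq()] on its inlier set and inliers are re-classified once
#' after the refit. Exits early when every point is an inlier.
#' Near-coplanar 4-point samples are rejected but still count toward
#' `max_iterations`. Fully reproducible given `seed` (R RNG).
#'
#' @param points n x 3 coordinate matrix, n >= 4.
#' @param threshold inlier distance threshold in Angstrom (default 1.0).
#' @param max_iterations maximum sampling iterations (default 100000).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return A `sphere_fit` with the final inlier set and RMSE.
#' @export
fit_sphere_ransac <- function(points, threshold = 1.0,
                              max_iterations = 100000L, seed = 0L) {
  pts <- .as_points(points)
  n <- nrow(pts)
  if (n < 4) stop("degenerate geometry: need >= 4 points, got ", n)
  if (threshold <= 0) stop("threshold must be > 0")
  res <- with_seed(seed,
                   .ransac_sphere_kernel(pts, threshold,
                                         as.integer(max_iterations)))
  if (!isTRUE(res$found))
    stop("sphere fit failed: no valid 4-point sample within ",
         max_iterations, " iterations (",
         res$n_valid_samples, " non-degenerate samples tried)")
  center <- res$center
  radius <- res$radius
  inl <- res$inlier_indices
  if (length(inl) >= 4) {
    refit <- tryCatch(fit_sphere_lsq(pts[inl, , drop = FALSE]),
                      error = function(e) NULL)
    if (!is.null(refit)) {
      # single re-classification pass against the refit sphere
      resid <- sqrt(rowSums(sweep(pts, 2, refit$center)^2)) - refit$radius
      inl2 <- which(abs(resid) <= threshold)
      if (length(inl2) >= 4) {
        center <- refit$center
        radius <- refit$radius
        inl <- inl2
      }
    }
  }
  resid <- sqrt(rowSums(sweep(pts[inl, , drop = FALSE], 2, center)^2)) -
    radius
  new_sphere_fit(center, radius, inl, sqrt(mean(resid^2)),
                 n_iterations_used = res$n_iterations_used,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
                 method = "ransac")
}

#' Concave/convex sign of a fitted surface
#'
#' Computes the centroid of all heavy atoms of the molecule (g_p) and of
#' the interfacial atoms (g_i), and the inner product
#' (g_p - g_i) . (center - g_i) with both vectors rooted at the
#' interfacial centroid. A negative product means the fitted sphere center
#' lies on the opposite side of the patch from the protein body: the patch
#' is concave (sign -1); positive means convex (sign +1).
#'
#' @param all_heavy_coords m x 3 coordinates of all heavy atoms of the
#'   molecule carrying the patch.
#' @param interfacial_coords n x 3 coordinates of the interfacial atoms.
#' @param sphere_center fitted sphere center (3-vector).
#' @return list with `sign` (-1 concave, +1 convex) and `dot_product`.
#' @export
surface_sign <- function(all_heavy_coords, interfacial_coords,
                         sphere_center) {
  allc <- .as_points(all_heavy_coords)
  intc <- .as_points(interfacial_coords)
  if (!nrow(allc) || !nrow(intc)) stop("coordinate lists must be non-empty")
  g_p <- colMeans(allc)
  g_i <- colMeans(intc)
  dp <- sum((g_p - g_i) * (as.numeric(sphere_center) - g_i))
  if (dp == 0)
    stop("indeterminate sign: inner product is exactly zero ",
         "(flat or centroid-coincident patch)")
  list(sign = if (dp < 0) -1L else 1L, dot_product = dp)
}

new_convexity_result <- function(fit, sign, dot_product, n_points) {
  structure(list(signed_convexity = sign / fit$radius,
                 radius = fit$radius, sign = sign,
                 inlier_fraction = length(fit$inlier_indices) / n_points,
                 dot_product = dot_product, fit = fit,
                 seed = fit$seed),
            class = "convexity_result")
}

#' @export
print.convexity_result <- function(x, ...) {
  cat("convexity:", format(x$signed_convexity, digits = 4), "1/A  (",
      if (x$sign < 0) "concave" else "convex",
      ", radius", format(x$radius, digits = 5), "A, inlier fraction",
      format(x$inlier_fraction, digits = 3), ")\n")
  invisible(x)
}

#' Signed convexity of an interfacial patch
#'
#' Fits a sphere to the interfacial heavy-atom coordinates by RANSAC and
#' signs the reciprocal radius with the concave/convex test of
#' [surface_sign()], using all heavy atoms of the named partner chains as
#' the molecule body.
#'
#' @param model a `structure_model`.
#' @param partner_chains chains forming the molecule that carries the
#'   patch.
#' @param interfacial either integer row indices into `model$atoms`, a
#'   data.frame with x/y/z columns (e.g. one side of an
#'   `interface_partition`), or an n x 3 coordinate matrix.
#' @param threshold,max_iterations,seed RANSAC parameters (see
#'   [fit_sphere_ransac()]).
#' @return A `convexity_result` with `signed_convexity = sign / radius`.
#' @export
signed_convexity <- function(model, partner_chains, interfacial,
                             threshold = 1.0, max_iterations = 100000L,
                             seed = 0L) {
  stopifnot(inherits(model, "structure_model"))
  if (is.numeric(interfacial) && is.null(dim(interfacial))) {
    rows <- model$atoms[as.integer(interfacial), , drop = FALSE]
    if (!all(rows$is_heavy)) stop("interfacial atoms must be heavy atoms")
    if (!all(rows$chain %in% partner_chains))
      stop("interfacial atoms must belong to partner_chains")
    pts <- atom_xyz(rows)
  } else if (is.data.frame(interfacial)) {
    pts <- atom_xyz(interfacial)
  } else {
    pts <- .as_points(interfacial)
  }
  if (nrow(pts) < 4)
    stop("need >= 4 interfacial atoms, got ", nrow(pts))
  body <- select_atoms(model, chains = partner_chains, heavy_only = TRUE)
  fit <- fit_sphere_ransac(pts, threshold = threshold,
                           max_iterations = max_iterations, seed = seed)
  sg <- surface_sign(atom_xyz(body), pts, fit$center)
  new_convexity_result(fit, sg$sign, sg$dot_product, nrow(pts))
}

#' Full interface profile of a two-partner complex
#'
#' Bundles the dSASA interface partition, the polar/apolar buried-area
#' split and the signed convexity of each partner's interfacial patch into
#' one record (one row of the summary table reported for optimized
#' binders: buried polar/apolar area and binder/target convexity).
#' A partner with fewer than 4 interfacial atoms yields `NA` convexity
#' with a warning rather than a failure.
#'
#' @param model a `structure_model` containing both partners.
#' @param partner_a,partner_b disjoint chain sets.
#' @param dsasa_threshold interfacial dSASA cutoff (Angstrom^2).
#' @param probe_radius,n_sphere_points SASA parameters.
#' @param ransac_threshold,ransac_iterations,seed RANSAC parameters.
#' @return An `interface_profile`: one-row data.frame with interfacial
#'   atom counts, buried polar/apolar/total areas and per-partner signed
#'   convexities, radii and inlier fractions.
#' @export
profile_interface <- function(model, partner_a, partner_b,
                              dsasa_threshold = 0.5, probe_radius = 1.4,
                              n_sphere_points = 960,
                              ransac_threshold = 1.0,
                              ransac_iterations = 100000L, seed = 0L) {
  part <- interfacial_atoms(model, partner_a, partner_b,
                            dsasa_threshold = dsasa_threshold,
                            probe_radius = probe_radius,
                            n_sphere_points = n_sphere_points)
  ba <- buried_area(part, model)
  cvx <- function(side, chains) {
    if (nrow(side) < 4) {
      warning("fewer than 4 interfacial atoms for partner [",
              paste(chains, collapse = ","), "]; convexity is NA")
      return(list(signed_convexity = NA_real_, radius = NA_real_,
                  sign = NA_integer_, inlier_fraction = NA_real_))
    }
    signed_convexity(model, chains, side, threshold = ransac_threshold,
                     max_iterations = ransac_iterations, seed = seed)
  }
  ca <- cvx(part$a, partner_a)
  cb <- cvx(part$b, partner_b)
  out <- data.frame(
    source_id = model$source_id,
    partner_a = paste(partner_a, collapse = ","),
    partner_b = paste(partner_b, collapse = ","),
    n_interfacial_a = nrow(part$a), n_interfacial_b = nrow(part$b),
    buried_polar = ba["total", "polar"],
    buried_apolar = ba["total", "apolar"],
    buried_total = ba["total", "total"],
    convexity_a = ca$signed_convexity, radius_a = ca$radius,
    sign_a = ca$sign, inlier_fraction_a = ca$inlier_fraction,
    convexity_b = cb$signed_convexity, radius_b = cb$radius,
    sign_b = cb$sign, inlier_fraction_b = cb$inlier_fraction,
    dsasa_threshold = dsasa_threshold,
    ransac_threshold = ransac_threshold,
    ransac_iterations = as.integer(ransac_iterations),
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
    stringsAsFactors = FALSE)
  class(out) <- c("interface_profile", "data.frame")
  attr(out, "partition") <- part
  attr(out, "buried_area") <- ba
  out
}

#' Write interface profiles as TSV
#' @param profiles an `interface_profile` (or several rbind-ed ones).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profiles, path) {
  write.table(as.data.frame(profiles), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
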