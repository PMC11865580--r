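# Five-helix scaffold screening and synthetic bundle generation.
#
# The generators are idealized stand-ins for a fragment-assembled scaffold
# library: they let the geometric admission rules (helix lengths, total
# length, concave interfacial face) be exercised and tested without any
# external design software. Loops between helices are reserved in the
# residue numbering but not built as atoms; helix detection treats the
# numbering gap as a chain break.

deg2rad <- function(x) x * pi / 180

cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("zero-length vector")
  v / n
}

#' Dihedral angle of four points
#'
#' Torsion a-b-c-d in degrees, right-handed convention, range (-180, 180].
#'
#' @param a,b,c,d 3-vectors.
#' @return angle in degrees.
#' @export
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unit3(b2))
  x <- sum(n1 * n2); y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

# Natural-extension-reference-frame placement: returns the position d such
# that |c-d| = bond, angle(b,c,d) = angle_deg and torsion(a,b,c,d) =
# torsion_deg.
place_atom <- function(a, b, c, bond, angle_deg, torsion_deg) {
  theta <- deg2rad(angle_deg); chi <- deg2rad(torsion_deg)
  d2 <- c(-bond * cos(theta),
          bond * sin(theta) * cos(chi),
          -bond * sin(theta) * sin(chi))
  bc <- unit3(c - b)
  n <- unit3(cross3(b - a, bc))
  m <- cross3(n, bc)
  M <- cbind(bc, m, n)
  as.numeric(M %*% d2 + c)
}

# Ideal backbone geometry (Engh-Huber-like) used by the generators.
.bb <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329,
            ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
            ca_cb = 1.521, ang_n_ca_cb = 110.4, improper_n_c_ca_cb = -122.6)

# Build an ideal polypeptide at fixed (phi, psi, omega); returns a list of
# per-residue named coordinate lists (N, CA, C, CB).
build_ideal_chain <- function(n_res, phi = -57, psi = -47, omega = 180,
                              with_cb = TRUE) {
  stopifnot(n_res >= 1)
  res <- vector("list", n_res)
  N <- c(0, 0, 0)
  CA <- c(.bb$n_ca, 0, 0)
  ang <- deg2rad(180 - .bb$ang_n_ca_c)
  C <- CA + .bb$ca_c * c(cos(ang), sin(ang), 0)
  res[[1]] <- list(N = N, CA = CA, C = C)
  for (i in seq_len(n_res - 1)) {
    p <- res[[i]]
    Nn <- place_atom(p$N, p$CA, p$C, .bb$c_n, .bb$ang_ca_c_n, psi)
    CAn <- place_atom(p$CA, p$C, Nn, .bb$n_ca, .bb$ang_c_n_ca, omega)
    Cn <- place_atom(p$C, Nn, CAn, .bb$ca_c, .bb$ang_n_ca_c, phi)
    res[[i + 1]] <- list(N = Nn, CA = CAn, C = Cn)
  }
  if (with_cb) {
    for (i in seq_len(n_res)) {
      p <- res[[i]]
      res[[i]]$CB <- place_atom(p$N, p$C, p$CA, .bb$ca_cb,
                                .bb$ang_n_ca_cb, .bb$improper_n_c_ca_cb)
    }
  }
  res
}

# Rotation matrix mapping unit vector a onto unit vector b (Rodrigues).
rotation_between <- function(a, b) {
  a <- unit3(a); b <- unit3(b)
  v <- cross3(a, b); s <- sqrt(sum(v^2)); cth <- sum(a * b)
  if (s < 1e-12) {
    if (cth > 0) return(diag(3))
    # opposite: rotate 180 deg about any axis perpendicular to a
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    axis <- unit3(cross3(a, p))
    return(2 * outer(axis, axis) - diag(3))
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx * ((1 - cth) / s^2)
}

#' Generate a parametric five-helix toy bundle
#'
#' Builds ideal alpha-helices (backbone N, CA, C plus CB) placed
#' antiparallel in two rows: the odd-numbered helices form the front
#' (interfacial) face, with their axes positioned on a circular arc of
#' radius `1/|face_curvature|` (a straight row when 0); the even-numbered
#' helices buttress behind. Negative `face_curvature` makes the front face
#' concave, positive convex. Loops of `loop_length` residues are reserved
#' in the numbering but not built. Deterministic given `seed` (the seed
#' only matters when `jitter_sd > 0`).
#'
#' @param n_helices number of helices (>= 2; default 5).
#' @param helix_length residues per helix.
#' @param loop_length residues reserved between consecutive helices.
#' @param face_curvature signed curvature of the front face in 1/Angstrom
#'   (|curvature| <= 0.2; negative = concave).
#' @param rise_per_residue helix rise along its axis (Angstrom).
#' @param helix_spacing arc-length spacing of front-row helix axes
#'   (Angstrom); back-row helices sit midway between, offset by
#'   `back_offset`.
#' @param back_offset distance of the back row behind the front row
#'   (Angstrom).
#' @param jitter_sd per-coordinate Gaussian jitter (Angstrom; 0 = none).
#' @param seed RNG seed for the jitter.
#' @return A `structure_model` (single chain A, residues ALA).
#' @export
make_toy_bundle <- function(n_helices = 5, helix_length = 19,
                            loop_length = 3, face_curvature = -0.05,
                            rise_per_residue = 1.5, helix_spacing = 10,
                            back_offset = 10, jitter_sd = 0, seed = 0L) {
  if (n_helices < 2) stop("n_helices must be >= 2")
  if (abs(face_curvature) > 0.2)
    stop("|face_curvature| must be <= 0.2 1/A")
  helix <- build_ideal_chain(helix_length)
  ca <- t(vapply(helix, function(r) r$CA, numeric(3)))
  axis <- prcomp(ca)$rotation[, 1]
  if (sum(axis * (ca[nrow(ca), ] - ca[1, ])) < 0) axis <- -axis
  R0 <- rotation_between(axis, c(0, 0, 1))
  ctr <- colMeans(ca)
  # template helix: axis along +z, CA centroid at origin
  template <- lapply(helix, function(r)
    lapply(r, function(p) as.numeric(R0 %*% (p - ctr))))
  # actual rise of the built helix is ~1.50 A/res; rescale z to the
  # requested rise so axial extent matches the parameters
  built_rise <- (template[[helix_length]]$CA[3] - template[[1]]$CA[3]) /
    (helix_length - 1)
  zscale <- rise_per_residue / built_rise
  template <- lapply(template, function(r)
    lapply(r, function(p) c(p[1], p[2], p[3] * zscale)))
  flipx <- diag(c(1, -1, -1))  # 180 deg about x: antiparallel partner

  n_front <- ceiling(n_helices / 2)
  curv <- face_curvature
  arc_xy <- function(s) {
    if (abs(curv) < 1e-9) return(c(s, 0))
    R <- 1 / abs(curv)
    th <- s / R
    # concave (curv < 0): front-row edges bend toward the face (-y);
    # convex: away (+y)
    c(R * sin(th), sign(curv) * R * (1 - cos(th)))
  }
  centers <- matrix(0, n_helices, 2)
  for (h in seq_len(n_helices)) {
    if (h %% 2 == 1) {
      f <- (h + 1) / 2
      s <- (f - (n_front + 1) / 2) * helix_spacing
      centers[h, ] <- arc_xy(s)
    } else {
      f <- h / 2
      s <- (f - (n_front + 1) / 2 + 0.5) * helix_spacing
      xy <- arc_xy(s)
      centers[h, ] <- c(xy[1], xy[2] + back_offset)
    }
  }
  dmin <- Inf
  for (i in seq_len(n_helices - 1))
    for (j in (i + 1):n_helices)
      dmin <- min(dmin, sqrt(sum((centers[i, ] - centers[j, ])^2)))
  if (dmin < 7)
    stop("helix clash: minimum axis distance ", format(dmin, digits = 3),
         " A < 7 A for the requested curvature/spacing")

  rows <- list()
  serial <- 0L
  for (h in seq_len(n_helices)) {
    flip <- h %% 2 == 0
    off <- c(centers[h, 1], centers[h, 2], 0)
    res0 <- (h - 1L) * (helix_length + loop_length)
    for (i in seq_len(helix_length)) {
      r <- template[[i]]
      for (nm in c("N", "CA", "C", "CB")) {
        p <- r[[nm]]
        if (flip) p <- as.numeric(flipx %*% p)
        p <- p + off
        serial <- serial + 1L
        rows[[serial]] <- data.frame(
          serial = serial, name = nm,
          element = if (nm == "N") "N" else "C",
          resid = "ALA", resno = res0 + i, chain = "A",
          x = p[1], y = p[2], z = p[3], stringsAsFactors = FALSE)
      }
    }
  }
  at <- do.call(rbind, rows)
  if (jitter_sd > 0)
    at[, c("x", "y", "z")] <- with_seed(seed,
      at[, c("x", "y", "z")] + rnorm(3 * nrow(at), 0, jitter_sd))
  new_structure_model(at, source_id = sprintf("toy_bundle_%+.3f",
                                              face_curvature))
}

#' Generate a synthetic ball-in-socket complex
#'
#' Two-chain fixture with known interface shape: chain B is a convex ball
#' of pseudo-atoms on a sphere; chain A is a concave socket (a
#' hemispherical shell facing the ball, backed by a second shell layer so
#' the socket body lies behind its interface). Used to exercise the
#' interface profiling end to end with known signs (+1 ball, -1 socket).
#'
#' @param ball_radius radius of the ball atom shell (Angstrom).
#' @param socket_radius radius of the socket inner shell (Angstrom).
#' @param n_ball,n_socket number of shell pseudo-atoms.
#' @param cap_angle half-opening of the socket cap in degrees.
#' @return A `structure_model` with chains A (socket) and B (ball).
#' @export
make_ball_socket <- function(ball_radius = 6, socket_radius = 10,
                             n_ball = 80, n_socket = 140, cap_angle = 80) {
  spiral <- function(n) {
    k <- seq_len(n) - 0.5
    z <- 1 - 2 * k / n
    r <- sqrt(pmax(0, 1 - z^2))
    phi <- pi * (3 - sqrt(5)) * (k - 0.5)
    cbind(r * cos(phi), r * sin(phi), z)
  }
  ball <- spiral(n_ball) * ball_radius
  dirs <- spiral(4 * n_socket)
  cap <- dirs[dirs[, 3] > cos(deg2rad(cap_angle)), , drop = FALSE]
  if (nrow(cap) > n_socket) cap <- cap[seq_len(n_socket), , drop = FALSE]
  # rotate the +z cap to face +x: shell directions seen from the ball
  # center (origin), so the bowl opens toward the ball automatically
  cap <- cap %*% t(rotation_between(c(0, 0, 1), c(1, 0, 0)))
  socket <- rbind(cap * socket_radius, cap * (socket_radius + 3.5))
  mk <- function(xyz, chain, off) {
    n <- nrow(xyz)
    data.frame(serial = off + seq_len(n), name = "CA", element = "C",
               resid = "ALA", resno = seq_len(n), chain = chain,
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
               stringsAsFactors = FALSE)
  }
  at <- rbind(mk(socket, "A", 0L), mk(ball, "B", nrow(socket)))
  new_structure_model(at, source_id = "ball_socket")
}

#' Assign helical segments from backbone dihedrals
#'
#' Residues are classified helical when their available backbone dihedrals
#' fall in `phi_range` x `psi_range`; terminal residues (and residues at
#' chain breaks, detected as non-consecutive residue numbering) are
#' classified on the dihedrals that exist. Isolated non-helical residues
#' surrounded by at least 3 helical residues in a window of 4 are smoothed
#' over; maximal helical runs of at least `min_run` residues become
#' segments, ordered N to C.
#'
#' @param model a `structure_model`.
#' @param chain chain to analyse (required when the model has several).
#' @param phi_range,psi_range helical dihedral windows in degrees.
#' @param min_run minimum segment length in residues.
#' @return data.frame of class `helix_segments`: segment, chain,
#'   start_residue, end_residue, length.
#' @export
assign_helices <- function(model, chain = NULL,
                           phi_range = c(-100, -30),
                           psi_range = c(-80, -5), min_run = 6) {
  stopifnot(inherits(model, "structure_model"))
  chains <- model_chains(model)
  if (is.null(chain)) {
    if (length(chains) > 1)
      stop("model has several chains (", paste(chains, collapse = ","),
           "); pick one with `chain`")
    chain <- chains
  }
  at <- select_atoms(model, chains = chain)
  resnos <- sort(unique(at$resno))
  if (length(resnos) < 8) stop("need >= 8 residues, got ", length(resnos))
  bb <- function(rn, nm) {
    row <- at[at$resno == rn & at$name == nm, , drop = FALSE]
    if (nrow(row) == 0)
      stop("residue ", rn, " (chain ", chain, ") lacks backbone atom ", nm)
    as.numeric(row[1, c("x", "y", "z")])
  }
  n <- length(resnos)
  phi <- psi <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i > 1 && resnos[i] - resnos[i - 1] == 1)
      phi[i] <- dihedral_angle(bb(resnos[i - 1], "C"), bb(resnos[i], "N"),
                               bb(resnos[i], "CA"), bb(resnos[i], "C"))
    if (i < n && resnos[i + 1] - resnos[i] == 1)
      psi[i] <- dihedral_angle(bb(resnos[i], "N"), bb(resnos[i], "CA"),
                               bb(resnos[i], "C"), bb(resnos[i + 1], "N"))
  }
  inr <- function(x, rng) !is.na(x) & x >= rng[1] & x <= rng[2]
  ok_phi <- inr(phi, phi_range); ok_psi <- inr(psi, psi_range)
  has <- !is.na(phi) | !is.na(psi)
  raw <- has & (is.na(phi) | ok_phi) & (is.na(psi) | ok_psi)
  # window-of-4 smoothing: recover single dropouts inside helical runs
  sm <- raw
  for (i in which(!raw)) {
    lo <- max(1, i - 2); hi <- min(n, lo + 3); lo <- max(1, hi - 3)
    if (sum(raw[lo:hi]) >= 3) sm[i] <- TRUE
  }
  # numbering discontinuities are chain breaks: segments never span them
  grp <- cumsum(c(1L, as.integer(diff(resnos) != 1L)))
  starts_all <- integer(); ends_all <- integer()
  for (g in unique(grp)) {
    idx <- which(grp == g)
    runs <- rle(sm[idx])
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    segs <- which(runs$values & runs$lengths >= min_run)
    starts_all <- c(starts_all, idx[starts[segs]])
    ends_all <- c(ends_all, idx[ends[segs]])
  }
  ord <- order(starts_all)
  starts_all <- starts_all[ord]; ends_all <- ends_all[ord]
  out <- data.frame(
    segment = seq_along(starts_all),
    chain = rep(chain, length(starts_all)),
    start_residue = resnos[starts_all],
    end_residue = resnos[ends_all],
    length = ends_all - starts_all + 1L)
  class(out) <- c("helix_segments", "data.frame")
  out
}

#' Interfacial-face atoms of a helix bundle
#'
#' Returns the CB coordinates (CA for residues lacking CB, e.g. glycine)
#' of residues on the designated face helices whose side chains point
#' toward the open face. The face direction is the component, orthogonal
#' to the bundle axis (first principal axis of the helix CA coordinates),
#' of the vector from the bundle centroid to the face-helix centroid;
#' residues with a positive CA->CB projection onto it are kept.
#'
#' @param model a `structure_model`.
#' @param helices a `helix_segments` table from [assign_helices()].
#' @param face_helix_indices which segments form the face (default 1, 3,
#'   5: the odd-numbered helices).
#' @param chain chain to use (single-chain models: automatic).
#' @param max_angle maximum angle (degrees) between the CA->CB vector and
#'   the face direction. The default 90 keeps every residue with a
#'   positive projection; a tighter cone (e.g. 30, used by
#'   [screen_scaffold()]) keeps only the face-presenting residue(s) of
#'   each helical turn.
#' @return n x 3 coordinate matrix with a `residues` attribute.
#' @export
concave_face_atoms <- function(model, helices,
                               face_helix_indices = c(1, 3, 5),
                               chain = NULL, max_angle = 90) {
  stopifnot(inherits(model, "structure_model"), is.data.frame(helices))
  if (any(face_helix_indices > nrow(helices)))
    stop("requested face helices ",
         paste(face_helix_indices, collapse = ","),
         " but only ", nrow(helices), " segments assigned")
  if (is.null(chain)) chain <- helices$chain[1]
  at <- select_atoms(model, chains = chain)
  in_seg <- function(rn, segs)
    vapply(rn, function(r)
      any(r >= segs$start_residue & r <= segs$end_residue), logical(1))
  ca <- at[at$name == "CA" & in_seg(at$resno, helices), , drop = FALSE]
  face_segs <- helices[face_helix_indices, , drop = FALSE]
  ca_face <- ca[in_seg(ca$resno, face_segs), , drop = FALSE]
  axis <- prcomp(atom_xyz(ca))$rotation[, 1]
  d0 <- colMeans(atom_xyz(ca_face)) - colMeans(atom_xyz(ca))
  d <- d0 - sum(d0 * axis) * axis
  if (sqrt(sum(d^2)) < 1e-6)
    stop("degenerate face: face-helix centroid coincides with the ",
         "bundle centroid")
  d <- unit3(d)
  min_cos <- cos(deg2rad(max_angle))
  keep <- list(); info <- list()
  for (rn in ca_face$resno) {
    cb <- at[at$resno == rn & at$name == "CB", , drop = FALSE]
    cai <- at[at$resno == rn & at$name == "CA", , drop = FALSE]
    if (nrow(cb)) {
      v <- as.numeric(cb[1, c("x", "y", "z")]) -
        as.numeric(cai[1, c("x", "y", "z")])
      if (sum(v * d) / sqrt(sum(v^2)) > max(min_cos, 0)) {
        keep[[length(keep) + 1]] <- as.numeric(cb[1, c("x", "y", "z")])
        info[[length(info) + 1]] <- rn
      }
    } else if (nrow(cai)) {
      keep[[length(keep) + 1]] <- as.numeric(cai[1, c("x", "y", "z")])
      info[[length(info) + 1]] <- rn
    }
  }
  if (length(keep) < 4)
    stop("degenerate face: only ", length(keep), " face atoms (< 4)")
  out <- do.call(rbind, keep)
  colnames(out) <- c("x", "y", "z")
  attr(out, "residues") <- unlist(info)
  attr(out, "face_direction") <- d
  out
}

#' Scaffold admission rules
#'
#' The geometric screen applied to candidate five-helix scaffolds: exactly
#' `n_helices` helices, every helix within the length band (the band
#' applies to all helices), total length under 120 residues, and a
#' concave interfacial face formed by the face helices.
#'
#' @param helix_len_min,helix_len_max helix length band (residues).
#' @param max_total_length maximum total length (residues; 119 = "under
#'   120").
#' @param n_helices required helix count.
#' @param face_helices indices of the face-forming helices.
#' @return list of rules for [screen_scaffold()].
#' @export
scaffold_rules <- function(helix_len_min = 18, helix_len_max = 22,
                           max_total_length = 119, n_helices = 5,
                           face_helices = c(1, 3, 5)) {
  list(helix_len_min = helix_len_min, helix_len_max = helix_len_max,
       max_total_length = max_total_length, n_helices = n_helices,
       face_helices = face_helices)
}

#' Screen a scaffold against the geometric admission rules
#'
#' Assigns helices, measures lengths, and computes the convexity sign of
#' the interfacial face (sphere fit on the face CB atoms, inner-product
#' sign test against the whole molecule). All verdicts are reported even
#' when one fails.
#'
#' @param model a `structure_model` (single chain).
#' @param rules a rule set from [scaffold_rules()].
#' @param chain chain id (single-chain models: automatic).
#' @param face_max_angle cone half-angle (degrees) for the face-atom
#'   selection. The screen defaults to 30: curvature is evaluated on the
#'   face-presenting CB of each helical turn, because grazing side chains
#'   trace their own helix ring and bias the sphere fit.
#' @param ransac_threshold,ransac_iterations,seed RANSAC parameters for
#'   the face sphere fit.
#' @return A `scaffold_screen` list: helix table, total_length,
#'   face_convexity, per-rule verdicts and overall `passes`.
#' @export
screen_scaffold <- function(model, rules = scaffold_rules(), chain = NULL,
                            face_max_angle = 30,
                            ransac_threshold = 1.0,
                            ransac_iterations = 100000L, seed = 0L) {
  helices <- assign_helices(model, chain = chain)
  chain <- helices$chain[1]
  at <- select_atoms(model, chains = chain)
  total_length <- max(at$resno) - min(at$resno) + 1L
  n_hel <- nrow(helices)
  verdicts <- c(
    n_helices = n_hel == rules$n_helices,
    total_length = total_length <= rules$max_total_length,
    helix_lengths = n_hel > 0 &&
      all(helices$length >= rules$helix_len_min &
            helices$length <= rules$helix_len_max))
  face <- NULL
  if (all(rules$face_helices <= n_hel)) {
    face_pts <- concave_face_atoms(model, helices,
                                   face_helix_indices = rules$face_helices,
                                   chain = chain,
                                   max_angle = face_max_angle)
    body <- select_atoms(model, chains = chain, heavy_only = TRUE)
    fit <- fit_sphere_ransac(face_pts, threshold = ransac_threshold,
                             max_iterations = ransac_iterations,
                             seed = seed)
    sg <- surface_sign(atom_xyz(body), face_pts, fit$center)
    face <- new_convexity_result(fit, sg$sign, sg$dot_product,
                                 nrow(face_pts))
    verdicts <- c(verdicts, concave_face = sg$sign == -1L)
  } else {
    verdicts <- c(verdicts, concave_face = FALSE)
  }
  structure(list(n_helices = n_hel, total_length = total_length,
                 helix_lengths = helices$length, helices = helices,
                 interfacial_helix_ids = rules$face_helices,
                 face_convexity = face, verdicts = verdicts,
                 passes = all(verdicts)),
            class = "scaffold_screen")
}

#' @export
print.scaffold_screen <- function(x, ...) {
  cat("scaffold screen:", if (x$passes) "PASS" else "FAIL", "\n")
  cat("  helices:", x$n_helices, "( lengths",
      paste(x$helix_lengths, collapse = ", "), ")\n")
  cat("  total length:", x$total_length, "residues\n")
  if (!is.null(x$face_convexity))
    cat("  face convexity:",
        format(x$face_convexity$signed_convexity, digits = 4), "1/A\n")
  cat("  verdicts:", paste(names(x$verdicts),
                           ifelse(x$verdicts, "ok", "FAIL"),
                           collapse = "; "), "\n")
  invisible(x)
}
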