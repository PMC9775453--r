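# Parametric generators with known ground truth: idealised cyclodextrins,
# host-guest assemblies, trajectories, phase-solubility datasets, and
# MM/GBSA frame tables.  Every stochastic element flows through an explicit
# seed; identical specs and seeds give bit-identical output.

# idealised 4C1 glucose chair: uniform bond 1.52 A, tetrahedral angles.
# ring radius and half-thickness of the chair hexagon:
CHAIR_BOND <- 1.52
CHAIR_R <- sqrt(8 / 9) * CHAIR_BOND      # 1.4331
CHAIR_D <- CHAIR_BOND / 6                # 0.2533
CO_BOND <- 1.43

#' Build specification for an idealised cyclodextrin
#'
#' @param o4_radius Mean O4-to-centroid distance, Angstrom (default 5.0,
#'   the beta-cyclodextrin range).
#' @param tilt Per-residue tilt angles in degrees (length 1 or 7).
#' @param ellipticity Target max/min ratio of the O4 centroid distances
#'   (>= 1).
#' @param rim_states Per-residue primary-rim rotamers, `"gg"`, `"gt"` or
#'   `"tg"` (length 1 or 7).
#' @param substitution `"native"`, `"2,6-di-O-methyl"`, `"permethyl"` or
#'   `"hydroxypropyl"`.
#' @param plane_noise SD of vertical O4 jitter, Angstrom (default 0).
#' @param seed RNG seed used when `plane_noise > 0`.
#' @return A list of class `"cd_build_spec"`.
#' @export
cd_build_spec <- function(o4_radius = 5.0, tilt = 0, ellipticity = 1,
                          rim_states = "gg", substitution = "native",
                          plane_noise = 0, seed = 1L) {
  if (o4_radius <= 0) stop("o4_radius must be positive")
  if (ellipticity < 1) stop("ellipticity must be >= 1")
  tilt <- rep_len(tilt, 7)
  rim_states <- rep_len(rim_states, 7)
  if (!all(rim_states %in% c("gg", "gt", "tg")))
    stop("rim_states must be gg, gt or tg")
  substitution <- match.arg(substitution,
                            c("native", "2,6-di-O-methyl", "permethyl",
                              "hydroxypropyl"))
  structure(list(n_units = 7L, o4_radius = o4_radius, tilt = tilt,
                 ellipticity = ellipticity, rim_states = rim_states,
                 substitution = substitution, plane_noise = plane_noise,
                 seed = seed),
            class = "cd_build_spec")
}

IDEAL_RIM <- list(gg = -60, gt = 60, tg = 180)  # omega of each ideal state

# O4 vertex positions: radius modulated so that max(d_K)/min(d_K) equals
# the requested ellipticity exactly over the seven actual vertex angles.
# Vertices run clockwise (seen from +z) so that each edge direction crossed
# with the outward radial gives +z, the primary-rim side.
o4_vertices <- function(radius, ellipticity, plane_noise = 0) {
  th <- -2 * pi * (0:6) / 7
  c2 <- cos(2 * th)
  wk <- (c2 - min(c2)) / (max(c2) - min(c2))
  r <- radius * (1 + (ellipticity - 1) * wk)
  v <- cbind(r * cos(th), r * sin(th), 0)
  if (plane_noise > 0) v[, 3] <- stats::rnorm(7, 0, plane_noise)
  v
}

# One glucose residue placed over the edge v_prev -> v_this.  Returns a
# named list of role -> coordinate.  `up` is the local primary-rim
# direction (unit); omega sets the O5-C5-C6-O6 torsion.
place_glucose <- function(v_prev, v_this, up, omega) {
  xhat <- unitv(v_this - v_prev)
  yhat <- unitv(vcross(up, xhat))       # horizontal, perpendicular to edge
  mid <- (v_prev + v_this) / 2
  # make yhat point outward (away from the macrocycle centre at the origin);
  # with clockwise vertex ordering xhat x yhat then points to the primary rim
  if (sum(yhat * mid) < 0) yhat <- -yhat

  # template chair, atom order O5 C1 C2 C3 C4 C5; the parity of the
  # alternating z-displacement selects the D-sugar enantiomer (4C1 pole at
  # Cremer-Pople theta = 0 and omega' - omega = +120 deg)
  k <- 0:5
  chair <- cbind(CHAIR_R * cos(pi * k / 3), CHAIR_R * sin(pi * k / 3),
                 -CHAIR_D * (-1)^k)
  rownames(chair) <- c("O5", "C1", "C2", "C3", "C4", "C5")
  # orthonormal template frame: a along C1->C4, b = ring normal made
  # perpendicular to a, c completes right-handed
  a <- unitv(chair["C4", ] - chair["C1", ])
  nt <- c(0, 0, 1)
  b <- unitv(nt - sum(nt * a) * a)
  cc <- vcross(a, b)
  # map a -> +xhat (C1 at the v_prev side) and the ring normal b to the
  # inward -yhat, which puts O5/C5/C6 on the primary (up) side of the edge
  # while keeping the mapping proper
  M <- cbind(xhat, -yhat, vcross(xhat, -yhat)) %*% rbind(a, b, cc)
  half14 <- vnorm(chair["C4", ] - chair["C1", ]) / 2
  gap <- vnorm(v_this - v_prev) / 2 - half14
  if (gap >= CO_BOND)
    stop("O4 polygon edge too long for the glucose template (radius too large)")
  w <- sqrt(CO_BOND^2 - gap^2)
  mid14 <- (chair["C1", ] + chair["C4", ]) / 2
  local <- sweep(chair, 2, mid14) %*% t(M)
  local <- sweep(local, 2, mid + w * yhat, `+`)
  rownames(local) <- rownames(chair)
  g <- lapply(seq_len(6), function(i) local[i, ])
  names(g) <- rownames(local)

  # exocyclic substituent directions: the two free tetrahedral directions
  # at a ring carbon, split by the local up vector
  tet_dirs <- function(center, n1, n2) {
    u1 <- unitv(n1 - center); u2 <- unitv(n2 - center)
    s <- -unitv(u1 + u2)
    t <- unitv(vcross(u1, u2))
    half <- 54.7356 * pi / 180
    list(cos(half) * s + sin(half) * t, cos(half) * s - sin(half) * t)
  }
  pick_dir <- function(dirs, sign_up) {
    z1 <- sum(dirs[[1]] * up); z2 <- sum(dirs[[2]] * up)
    if (sign_up > 0) dirs[[if (z1 >= z2) 1 else 2]]
    else dirs[[if (z1 < z2) 1 else 2]]
  }
  d2 <- tet_dirs(g$C2, g$C1, g$C3)
  g$O2 <- g$C2 + CO_BOND * pick_dir(d2, -1)      # secondary rim: down
  d3 <- tet_dirs(g$C3, g$C2, g$C4)
  g$O3 <- g$C3 + CO_BOND * pick_dir(d3, -1)
  # C6 takes the D-glucose branch at C5, identified by the azimuthal order
  # of O5 and C4 about the C5-C6 axis (omega' - omega = +120 degrees)
  d5 <- tet_dirs(g$C5, g$C4, g$O5)
  for (dir in d5) {
    c6 <- g$C5 + CHAIR_BOND * dir
    probe <- place_atom(g$O5, g$C5, c6, CO_BOND, 109.4712, 0)
    diff <- dihedral(g$C4, g$C5, c6, probe)
    if (abs(((diff - 120) + 180) %% 360 - 180) < 30) { g$C6 <- c6; break }
  }
  if (is.null(g$C6)) g$C6 <- g$C5 + CHAIR_BOND * d5[[1]]
  g$O6 <- place_atom(g$O5, g$C5, g$C6, CO_BOND, 109.4712, omega)
  g
}

# Rim substituents are placed anti-periplanar across the O-C ether bond so
# that neighbouring residues' substituents stay out of covalent range.
attach_substituents <- function(g, substitution) {
  if (substitution == "2,6-di-O-methyl") {
    g$CM2 <- place_atom(g$C3, g$C2, g$O2, CO_BOND, 109.4712, 180)
    g$CM6 <- place_atom(g$C5, g$C6, g$O6, CO_BOND, 109.4712, 180)
  } else if (substitution == "permethyl") {
    g$CM2 <- place_atom(g$C3, g$C2, g$O2, CO_BOND, 109.4712, 180)
    g$CM3 <- place_atom(g$C2, g$C3, g$O3, CO_BOND, 109.4712, -60)
    g$CM6 <- place_atom(g$C5, g$C6, g$O6, CO_BOND, 109.4712, 180)
  } else if (substitution == "hydroxypropyl") {
    g$CP1 <- place_atom(g$C3, g$C2, g$O2, CO_BOND, 109.4712, 180)
    g$CP2 <- place_atom(g$C2, g$O2, g$CP1, CHAIR_BOND, 109.4712, 180)
    g$CP3 <- place_atom(g$O2, g$CP1, g$CP2, CHAIR_BOND, 109.4712, 60)
    g$OP2 <- place_atom(g$O2, g$CP1, g$CP2, CO_BOND, 109.4712, -60)
  }
  g
}

#' Build an idealised cyclodextrin
#'
#' Places seven 4C1-template glucose units over the edges of an O4 heptagon
#' of the requested radius/ellipticity, applies per-residue rigid tilts
#' about the local O4-O4 edge (positive tilts lean the primary rim toward
#' the cavity axis), sets the primary-rim torsions to the ideal angle of the
#' requested rotamer state, and attaches rim substituents.  The ground
#' truth of every set parameter is returned alongside.
#'
#' @param spec A [cd_build_spec()].
#' @return List: `structure` (a Cartesian [crystal_structure()]), `truth`
#'   (list with the set `tilt`, `o4_radius`, `ellipticity`, `rim_states`,
#'   `substitution`, `axis` = +z, `o4_vertices`).
#' @examples
#' cd <- build_ideal_cd(cd_build_spec(tilt = 10))
#' host <- annotate_cd(cd$structure)[[1]]
#' round(tilt_angle(host), 2)
#' @export
build_ideal_cd <- function(spec = cd_build_spec()) {
  stopifnot(inherits(spec, "cd_build_spec"))
  if (spec$plane_noise > 0) set.seed(spec$seed)
  v <- o4_vertices(spec$o4_radius, spec$ellipticity, spec$plane_noise)
  up <- c(0, 0, 1)
  rows <- list()
  for (n in 1:7) {
    prev <- ((n - 2) %% 7) + 1
    g <- place_glucose(v[prev, ], v[n, ], up, IDEAL_RIM[[spec$rim_states[n]]])
    g <- attach_substituents(g, spec$substitution)
    g$O4 <- v[n, ]
    if (abs(spec$tilt[n]) > 1e-12) {
      R <- rotation_about(unitv(v[n, ] - v[prev, ]), spec$tilt[n])
      g <- lapply(g, function(p)
        as.numeric(R %*% (p - v[n, ])) + v[n, ])
    }
    for (role in names(g))
      rows[[length(rows) + 1L]] <- data.frame(
        label = sprintf("%s_%d", role, n),
        element = substr(role, 1, 1),
        x = g[[role]][1], y = g[[role]][2], z = g[[role]][3],
        residue_id = n, stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, rows)
  st <- crystal_structure(atoms, coord_system = "cartesian")
  list(structure = st,
       truth = list(tilt = spec$tilt, o4_radius = spec$o4_radius,
                    ellipticity = spec$ellipticity,
                    rim_states = spec$rim_states,
                    substitution = spec$substitution,
                    axis = c(0, 0, 1), o4_vertices = v))
}

# ---- guest ----------------------------------------------------------------

# Piperine-like three-fragment guest: planar aromatic six-ring, a short
# conjugated linker, and a chair six-ring with one nitrogen.  Generic
# geometry (no force-field realism); rings are labelled GA* and GP* so they
# can be selected by name.
build_guest_template <- function() {
  th <- pi / 3 * (0:5)
  ringA <- cbind(1.39 * cos(th), 1.39 * sin(th), 0)
  linker <- cbind(0.35 * (1:4), 0, 0.95 * (1:4))
  k <- 0:5
  chair <- cbind(CHAIR_R * cos(pi * k / 3), CHAIR_R * sin(pi * k / 3),
                 CHAIR_D * (-1)^k)
  ringP <- sweep(chair, 2, c(0.35 * 4 + 0.8, 0, 0.95 * 4 + 1.2), `+`)
  xyz <- rbind(ringA, linker, ringP)
  labels <- c(sprintf("GA%d", 1:6), sprintf("GL%d", 1:4), sprintf("GP%d", 1:6))
  elements <- c(rep("C", 6), rep("C", 4), c("N", rep("C", 5)))
  list(xyz = xyz, labels = labels, elements = elements,
       ringA = 1:6, ringP = 11:16)
}

#' Build specification for a host-guest complex
#'
#' @param hosts List of [cd_build_spec()]s (1 to 4 hosts).
#' @param orientations Orientation of each host after the first relative to
#'   the previous one: `"head-to-tail"`, `"tail-to-tail"` or
#'   `"head-to-head"`.
#' @param axial_shift Centroid separation along the stack axis between
#'   consecutive hosts, Angstrom.
#' @param lateral_offset Perpendicular centroid offset, Angstrom.
#' @param interplanar_angle Tilt of each later host's O4 plane against the
#'   first, degrees.
#' @param guest `TRUE` to thread the piperine-like template guest.
#' @param guest_depth Position of the guest aromatic-ring centroid along
#'   the first host's axis, Angstrom from its O4 plane (positive toward
#'   the primary rim).
#' @param guest_angle Angle of the aromatic ring plane to the first host's
#'   O4 plane, degrees.
#' @return A list of class `"complex_build_spec"`.
#' @export
complex_build_spec <- function(hosts = list(cd_build_spec()),
                               orientations = "head-to-tail",
                               axial_shift = 8, lateral_offset = 0,
                               interplanar_angle = 0,
                               guest = TRUE, guest_depth = 0,
                               guest_angle = 0) {
  if (inherits(hosts, "cd_build_spec")) hosts <- list(hosts)
  if (!length(hosts) || length(hosts) > 4)
    stop("1 to 4 hosts supported")
  npair <- max(0L, length(hosts) - 1L)
  orientations <- rep_len(orientations, max(1L, npair))
  if (!all(orientations %in% c("head-to-tail", "tail-to-tail", "head-to-head")))
    stop("unknown orientation label")
  structure(list(hosts = hosts, orientations = orientations,
                 axial_shift = rep_len(axial_shift, max(1L, npair)),
                 lateral_offset = rep_len(lateral_offset, max(1L, npair)),
                 interplanar_angle = rep_len(interplanar_angle, max(1L, npair)),
                 guest = guest, guest_depth = guest_depth,
                 guest_angle = guest_angle),
            class = "complex_build_spec")
}

#' Build a host-guest complex
#'
#' Hosts are stacked along +z in the requested orientations (each placed
#' above the previous); the guest is threaded along the shared axis.
#' Orientation semantics (axes oriented secondary rim to primary rim):
#' head-to-tail keeps both axes parallel; tail-to-tail flips the upper host
#' so the primary (narrow) rims face; head-to-head flips it and stacks it
#' below so the secondary (wide) rims face.
#'
#' @param spec A [complex_build_spec()].
#' @return List: `structure` (all atoms), `truth` (placement parameters and
#'   per-host atom index ranges plus guest ring indices).
#' @export
build_complex <- function(spec = complex_build_spec()) {
  stopifnot(inherits(spec, "complex_build_spec"))
  all_atoms <- list()
  host_ranges <- list()
  z_cursor <- 0
  prev_flip <- FALSE
  for (h in seq_along(spec$hosts)) {
    cd <- build_ideal_cd(spec$hosts[[h]])
    at <- cd$structure$atoms
    flip <- prev_flip
    offset <- c(0, 0, z_cursor)
    if (h > 1) {
      k <- h - 1
      ori <- spec$orientations[k]
      flip <- switch(ori, "head-to-tail" = prev_flip, !prev_flip)
      below <- ori == "head-to-head"
      dz <- if (below) -spec$axial_shift[k] else spec$axial_shift[k]
      z_cursor <- z_cursor + dz
      offset <- c(spec$lateral_offset[k], 0, z_cursor)
    }
    xyz <- as.matrix(at[, c("x", "y", "z")])
    if (flip) xyz <- xyz %*% diag(c(1, -1, -1))   # 180 deg about x
    if (h > 1 && abs(spec$interplanar_angle[h - 1]) > 1e-12)
      xyz <- xyz %*% t(rotation_about(c(1, 0, 0), spec$interplanar_angle[h - 1]))
    xyz <- sweep(xyz, 2, offset, `+`)
    at[, c("x", "y", "z")] <- xyz
    at$label <- sprintf("%s%d_%s", LETTERS[h], at$residue_id, at$label)
    at$residue_id <- at$residue_id + (h - 1) * 7L
    start <- sum(vapply(all_atoms, nrow, 0L)) + 1L
    all_atoms[[length(all_atoms) + 1L]] <- at
    host_ranges[[h]] <- start:(start + nrow(at) - 1L)
    prev_flip <- flip
  }
  guest_idx <- NULL
  if (isTRUE(spec$guest)) {
    g <- build_guest_template()
    xyz <- g$xyz
    # the ring-plane angle is set by rotating the aromatic ring about its
    # own centroid, so the guest stays threaded along the axis at any angle
    if (abs(spec$guest_angle) > 1e-12)
      xyz[g$ringA, ] <- rotate_coords(xyz[g$ringA, , drop = FALSE],
                                      rotation_about(c(1, 0, 0),
                                                     spec$guest_angle),
                                      origin = colMeans(xyz[g$ringA, ]))
    xyz <- sweep(xyz, 2, c(0, 0, spec$guest_depth), `+`)
    start <- sum(vapply(all_atoms, nrow, 0L)) + 1L
    all_atoms[[length(all_atoms) + 1L]] <-
      data.frame(label = g$labels, element = g$elements,
                 x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                 occupancy = 1, residue_id = 7L * length(spec$hosts) + 1L,
                 alt_site = NA_character_, stringsAsFactors = FALSE)
    guest_idx <- list(ringA = start - 1L + g$ringA,
                      ringP = start - 1L + g$ringP)
  }
  atoms <- do.call(rbind, all_atoms)
  st <- crystal_structure(atoms, coord_system = "cartesian")
  # clash check between entities (covalent distances within an entity are
  # of course below the threshold)
  xyzall <- coords(st)
  groups <- c(host_ranges, if (!is.null(guest_idx))
    list(min(unlist(guest_idx)):nrow(atoms)))
  for (i in seq_along(groups)) for (j in seq_along(groups)) {
    if (i >= j) next
    a <- xyzall[groups[[i]], , drop = FALSE]
    b <- xyzall[groups[[j]], , drop = FALSE]
    dmin <- sqrt(min(outer(rowSums(a^2), rowSums(b^2), `+`) -
                       2 * a %*% t(b)))
    if (is.finite(dmin) && dmin < 1.5) {
      warning(sprintf("overlapping heavy atoms between entities %d and %d (min %.2f A)",
                      i, j, dmin))
      break
    }
  }
  list(structure = st,
       truth = list(orientations = spec$orientations,
                    axial_shift = spec$axial_shift,
                    lateral_offset = spec$lateral_offset,
                    interplanar_angle = spec$interplanar_angle,
                    guest_depth = spec$guest_depth,
                    guest_angle = spec$guest_angle,
                    host_ranges = host_ranges, guest = guest_idx))
}

# ---- trajectories ---------------------------------------------------------

#' Build a synthetic trajectory
#'
#' Seeded isotropic Gaussian jitter per atom per frame, plus a
#' deterministic per-frame drift applied to a selection (frame 1 is the
#' undrifted base).
#'
#' @param base A [crystal_structure()] or `n x 3` coordinate matrix.
#' @param n_frames Number of frames.
#' @param jitter_sd Jitter SD, Angstrom (>= 0).
#' @param drift Length-3 displacement added per frame (Angstrom/frame).
#' @param drift_selection Atom indices receiving the drift (default all).
#' @param timestep ps per frame.
#' @param seed RNG seed.
#' @return A [trajectory()].
#' @export
build_trajectory <- function(base, n_frames = 10, jitter_sd = 0,
                             drift = c(0, 0, 0), drift_selection = NULL,
                             timestep = 1, seed = 1L) {
  if (jitter_sd < 0) stop("jitter_sd must be >= 0")
  xyz <- if (inherits(base, "crystal_structure")) coords(as_cartesian(base))
  else as.matrix(base)
  nat <- nrow(xyz)
  if (is.null(drift_selection)) drift_selection <- seq_len(nat)
  set.seed(seed)
  frames <- lapply(seq_len(n_frames), function(k) {
    f <- xyz
    if (jitter_sd > 0)
      f <- f + matrix(stats::rnorm(3 * nat, 0, jitter_sd), nat, 3)
    f[drift_selection, ] <- f[drift_selection, , drop = FALSE] +
      matrix((k - 1) * drift, length(drift_selection), 3, byrow = TRUE)
    f
  })
  atoms <- if (inherits(base, "crystal_structure"))
    base$atoms[, c("label", "element", "residue_id")] else NULL
  trajectory(frames, timestep = timestep, atoms = atoms)
}

# ---- phase-solubility -----------------------------------------------------

#' Specification for a synthetic phase-solubility dataset
#'
#' Defaults emulate the study conditions of a poorly water-soluble guest
#' titrated against a cyclodextrin: an intrinsic solubility of a few
#' hundredths of a millimolar, CD levels of 1-15 mM for the aggregating
#' (B-type) native host and 1-60 mM for soluble derivatives.
#'
#' @param profile `"A_L"`, `"B_s"` or `"B_i"`.
#' @param s0_mM Solubility in pure water, mM (default 0.0378).
#' @param slope Phase-solubility slope in (0, 1).
#' @param intercept Line intercept in mM (default `s0_mM`; A_L systems of
#'   poorly soluble guests often have negative fitted intercepts, which is
#'   why S0 stays a separate argument downstream).
#' @param cd_max Highest CD level, mM (default 15 for B types, 60
#'   otherwise).
#' @param n_levels Number of ascending CD levels (defaults: 10 for A_L over
#'   1-60 mM, 15 for B types over 1-15 mM).
#' @param plateau_start CD level (mM) where a B-type profile stops rising.
#' @param plateau_levels Number of near-maximum levels before the decline
#'   (default 2; >= 2 gives B_s, fewer gives B_i).
#' @param decline_rate Post-plateau decline, mM of guest per mM of CD.
#' @param noise_rel Relative Gaussian noise per replicate (default 0).
#' @param n_replicates Replicates per level (default 3).
#' @param seed RNG seed.
#' @export
solubility_gen_spec <- function(profile = c("A_L", "B_s", "B_i"),
                                s0_mM = 0.0378, slope = 0.1562,
                                intercept = NULL,
                                cd_max = NULL, n_levels = NULL,
                                plateau_start = 3, plateau_levels = 2,
                                decline_rate = 0.02, noise_rel = 0,
                                n_replicates = 3, seed = 1L) {
  profile <- match.arg(profile)
  if (slope <= 0 || slope >= 1) stop("slope must lie in (0, 1)")
  if (noise_rel < 0) stop("noise_rel must be >= 0")
  if (is.null(cd_max)) cd_max <- if (profile == "A_L") 60 else 15
  if (is.null(n_levels)) n_levels <- if (profile == "A_L") 10 else 15
  if (is.null(intercept)) intercept <- s0_mM
  structure(list(profile = profile, s0_mM = s0_mM, slope = slope,
                 intercept = intercept, cd_max = cd_max,
                 n_levels = n_levels, plateau_start = plateau_start,
                 plateau_levels = if (profile == "B_i") 0L else plateau_levels,
                 decline_rate = decline_rate, noise_rel = noise_rel,
                 n_replicates = n_replicates, seed = seed),
            class = "solubility_gen_spec")
}

#' Generate a synthetic phase-solubility dataset
#'
#' A_L: `S(C) = intercept + slope * C`.  B types: linear up to
#' `plateau_start`, flat for `plateau_levels` levels (B_s) or none (B_i),
#' then declining at `decline_rate`.  Per-replicate multiplicative Gaussian
#' noise of relative SD `noise_rel`; level means and SDs are recorded.
#'
#' @param spec A [solubility_gen_spec()].
#' @return List: `dataset` (a [solubility_dataset()]) and `truth` (the set
#'   slope, intercept, s0, profile, and the implied Kc and CE).
#' @export
gen_solubility <- function(spec = solubility_gen_spec()) {
  stopifnot(inherits(spec, "solubility_gen_spec"))
  conc <- seq(1, spec$cd_max, length.out = spec$n_levels)
  mu <- spec$intercept + spec$slope * conc
  if (any(mu < 0))
    stop("intercept/slope give negative solubility at the lowest CD level; ",
         "raise the intercept or the lowest level")
  if (spec$profile != "A_L") {
    i_lin <- which(conc <= spec$plateau_start)
    s_max <- spec$intercept + spec$slope * spec$plateau_start
    for (i in seq_along(conc)) {
      if (i %in% i_lin) next
      n_plateau <- sum(!(seq_len(i - 1) %in% i_lin))
      if (n_plateau < spec$plateau_levels) mu[i] <- s_max
      else {
        c_decline <- conc[max(i_lin) + spec$plateau_levels]
        mu[i] <- max(0, s_max - spec$decline_rate * (conc[i] - c_decline))
      }
    }
  }
  set.seed(spec$seed)
  if (spec$noise_rel > 0) {
    reps <- vapply(mu, function(m)
      m * (1 + stats::rnorm(spec$n_replicates, 0, spec$noise_rel)),
      numeric(spec$n_replicates))
    reps <- matrix(reps, nrow = spec$n_replicates)
    y <- pmax(colMeans(reps), 0)
    sdv <- apply(reps, 2, stats::sd)
  } else {
    y <- mu
    sdv <- rep(0, length(mu))
  }
  ds <- solubility_dataset(conc, y, sd = sdv,
                           n_replicates = spec$n_replicates)
  list(dataset = ds,
       truth = list(profile = spec$profile, slope = spec$slope,
                    intercept = spec$intercept, s0_mM = spec$s0_mM,
                    kc = compute_kc(spec$slope, spec$s0_mM),
                    ce = compute_ce(spec$slope)))
}

# ---- MM/GBSA frames -------------------------------------------------------

#' Specification for a synthetic MM/GBSA frame table
#'
#' Defaults reproduce the component scale of a cyclodextrin inclusion
#' complex: tens of kcal/mol of favourable van der Waals energy, a smaller
#' electrostatic term, an unfavourable polar solvation term and a small
#' negative nonpolar term, with per-frame SDs of a few kcal/mol and
#' positively correlated components.
#'
#' @param means Named numeric: `dE_vdW`, `dE_ele`, `dG_GB`, `dG_nonpolar`
#'   (kcal/mol).
#' @param sds Matching SDs (kcal/mol, >= 0).
#' @param correlation Pairwise correlation of all components (scalar in
#'   (-1, 1)) or a full 4 x 4 positive semi-definite matrix.
#' @param tds Scalar TdS carried into the ground truth (normal-mode
#'   convention, printed sign), or `NULL`.
#' @param n_frames Number of frames.
#' @param seed RNG seed.
#' @export
energy_gen_spec <- function(means = c(dE_vdW = -51.70, dE_ele = -10.41,
                                      dG_GB = 26.68, dG_nonpolar = -5.44),
                            sds = c(dE_vdW = 4.08, dE_ele = 4.64,
                                    dG_GB = 3.91, dG_nonpolar = 0.30),
                            correlation = 0, tds = NULL,
                            n_frames = 1000, seed = 1L) {
  means <- means[ENERGY_BASE]; sds <- sds[ENERGY_BASE]
  if (anyNA(means) || anyNA(sds)) stop("means and sds must name all of: ",
                                       paste(ENERGY_BASE, collapse = ", "))
  if (any(sds < 0)) stop("sds must be >= 0")
  if (is.matrix(correlation)) {
    C <- correlation
  } else {
    C <- matrix(correlation, 4, 4); diag(C) <- 1
  }
  ch <- try(chol(C), silent = TRUE)
  if (inherits(ch, "try-error"))
    stop("correlation matrix is not positive semi-definite")
  structure(list(means = means, sds = sds, correlation = C, tds = tds,
                 n_frames = n_frames, seed = seed),
            class = "energy_gen_spec")
}

#' Generate a synthetic MM/GBSA frame table
#'
#' Correlated Gaussian component draws, constructively recentred and
#' rescaled so the sample means and SDs equal the specification exactly
#' (the correlation remains approximate).
#'
#' @param spec An [energy_gen_spec()].
#' @return List: `table` (an [energy_frames()]) and `truth` (the exact
#'   means/SDs plus the derived means from [summarize_means()]).
#' @export
gen_energy_frames <- function(spec = energy_gen_spec()) {
  stopifnot(inherits(spec, "energy_gen_spec"))
  set.seed(spec$seed)
  n <- spec$n_frames
  Z <- matrix(stats::rnorm(n * 4), n, 4)
  X <- Z %*% chol(spec$correlation)
  for (j in 1:4) {
    v <- X[, j]
    if (n > 1 && stats::sd(v) > 0) v <- (v - mean(v)) / stats::sd(v)
    else v <- rep(0, n)
    X[, j] <- spec$means[j] + spec$sds[j] * v
  }
  colnames(X) <- ENERGY_BASE
  tab <- energy_frames(as.data.frame(X))
  truth <- list(means = spec$means, sds = spec$sds, tds = spec$tds,
                derived = summarize_means(c(as.list(spec$means),
                                            list(TdS = spec$tds))))
  list(table = tab, truth = truth)
}
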