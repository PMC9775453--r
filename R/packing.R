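# Host-pair and guest-host arrangement, packing mode, and contact detection.

#' Host-pair geometry and orientation class
#'
#' Interplanar angle between the two O4 mean planes (folded to \[0, 90\]),
#' centroid separation and its decomposition into an axial shift and a
#' lateral offset against the bisector of the two oriented cavity axes, and
#' the orientation class.  Axes are oriented secondary-to-primary rim;
#' classification by dot-product sign (threshold 0.5): axes parallel gives
#' head-to-tail; antiparallel with the primary rims facing gives
#' tail-to-tail, with the secondary rims facing head-to-head.  Oblique axis
#' arrangements raise a warning and are classified by the nearest signs.
#'
#' @param hostA,hostB Annotated [cd_host] objects.
#' @return List of class `"host_pair_geometry"`: `interplanar_angle`,
#'   `centroid_distance`, `lateral_offset`, `axial_shift`, `orientation`.
#' @export
host_pair_geometry <- function(hostA, hostB) {
  axA <- cd_axis(hostA); axB <- cd_axis(hostB)
  ang <- fold_angle(axA$direction, axB$direction)
  dvec <- axB$anchor - axA$anchor
  cdist <- vnorm(dvec)
  # bisector of the two oriented axes (sign-symmetrised so the result does
  # not depend on argument order)
  bis <- axA$direction + sign(sum(axA$direction * axB$direction) + 1e-15) * axB$direction
  if (vnorm(bis) < 1e-9) bis <- axA$direction
  bis <- unitv(bis)
  axial <- abs(sum(dvec * bis))
  lateral <- vnorm(dvec - sum(dvec * bis) * bis)
  dot_ab <- sum(axA$direction * axB$direction)
  if (abs(dot_ab) < 0.5)
    warning(sprintf("oblique host arrangement (axis dot product %.2f); orientation class is approximate", dot_ab))
  if (dot_ab >= 0) {
    orientation <- "head-to-tail"
  } else {
    dhat <- if (cdist > 1e-9) dvec / cdist else axA$direction
    sA <- sum(axA$direction * dhat)   # >0: A's primary rim points at B
    sB <- sum(axB$direction * dhat)   # <0: B's primary rim points at A
    orientation <- if (sA >= 0) "tail-to-tail" else "head-to-head"
    if (abs(sA) < 0.5 && cdist > 1e-9)
      warning("hosts are side-by-side rather than stacked; facing class is approximate")
  }
  structure(list(interplanar_angle = ang, centroid_distance = cdist,
                 lateral_offset = lateral, axial_shift = axial,
                 orientation = orientation),
            class = "host_pair_geometry")
}

#' @export
print.host_pair_geometry <- function(x, ...) {
  cat(sprintf("Host pair: %s, interplanar angle %.2f deg, centroid distance %.3f A (axial %.3f, lateral %.3f)\n",
              x$orientation, x$interplanar_angle, x$centroid_distance,
              x$axial_shift, x$lateral_offset))
  invisible(x)
}

#' Guest ring orientation relative to a host
#'
#' Angle between the best-fit plane of a guest ring and the host O4 plane,
#' folded to \[0, 90\] degrees, plus the signed penetration depth of the
#' ring centroid along the host axis (positive toward the primary rim).
#'
#' @param guest_ring Coordinates (>= 5 atoms) of the ring, `n x 3` matrix.
#' @param host A [cd_host].
#' @param planarity_rms Warn when the ring deviates from planarity by more
#'   than this rms (Angstrom, default 0.2).
#' @return List of class `"guest_orientation"`: `ring_plane_angle`,
#'   `penetration_depth`.
#' @export
guest_orientation <- function(guest_ring, host, planarity_rms = 0.2) {
  guest_ring <- as.matrix(guest_ring)
  if (nrow(guest_ring) < 5) stop("need at least 5 ring atoms")
  gplane <- fit_mean_plane(guest_ring)
  if (gplane$rms_dev > planarity_rms)
    warning(sprintf("guest ring deviates from planarity (rms %.3f A)", gplane$rms_dev))
  ax <- cd_axis(host)
  o4plane <- fit_mean_plane(host_role_coords(host, "O4"), orient = ax$direction)
  ang <- fold_angle_planes(gplane$normal, o4plane$normal)
  depth <- sum((gplane$point - ax$anchor) * ax$direction)
  structure(list(ring_plane_angle = ang, penetration_depth = depth),
            class = "guest_orientation")
}

# dihedral angle between two planes from their normals, folded to [0, 90]
fold_angle_planes <- function(n1, n2) fold_angle(n1, n2)

#' @export
print.guest_orientation <- function(x, ...) {
  cat(sprintf("Guest ring: %.2f deg to the O4 plane, depth %+.3f A along the axis\n",
              x$ring_plane_angle, x$penetration_depth))
  invisible(x)
}

#' Crystal packing mode of stacked complex units
#'
#' For consecutive units stacked along an axis, the successive shift is the
#' magnitude of the component of each centroid-to-centroid vector
#' perpendicular to the stacking direction.  Units whose successive shifts
#' all stay at or below `ch_threshold` stack into continuous channels
#' (`"CH"` mode); larger shifts give `"other"`.
#'
#' @param units List (length >= 2) of [crystal_structure()]s or `n x 3`
#'   coordinate matrices, in stacking order.
#' @param stacking_axis Length-3 direction of the stacking axis (Cartesian),
#'   or a cell-axis name `"a"`, `"b"`, `"c"` resolved against the first
#'   unit's cell under the package orthogonalisation convention.
#' @param ch_threshold Channel-mode shift threshold, Angstrom
#'   (default 3.2, covering the 2.7-3.1 range typical of channel-packed
#'   cyclodextrin dimers).
#' @param cd_axis_direction Optional axis direction of the repeating unit,
#'   for the axis-to-cell-axis angle; computed as `NA` when absent.
#' @return List of class `"packing_mode"`: `successive_shift` (vector),
#'   `mode`, `axis_cell_angle`.
#' @export
packing_mode <- function(units, stacking_axis = "c", ch_threshold = 3.2,
                         cd_axis_direction = NULL) {
  if (length(units) < 2) stop("need at least 2 stacked units")
  cents <- t(vapply(units, function(u) {
    xyz <- if (inherits(u, "crystal_structure")) coords(u) else as.matrix(u)
    colMeans(xyz)
  }, numeric(3)))
  if (is.character(stacking_axis)) {
    u1 <- units[[1]]
    if (!inherits(u1, "crystal_structure") || is.null(u1$cell))
      stop("a cell-axis name needs a first unit with a unit cell")
    M <- orthogonalization_matrix(u1$cell)
    stacking_axis <- M[, match(stacking_axis, c("a", "b", "c"))]
  }
  shat <- unitv(stacking_axis)
  dvec <- cents[-1, , drop = FALSE] - cents[-nrow(cents), , drop = FALSE]
  shifts <- apply(dvec, 1, function(v) vnorm(v - sum(v * shat) * shat))
  axis_angle <- if (is.null(cd_axis_direction)) NA_real_ else
    fold_angle(cd_axis_direction, shat)
  structure(list(successive_shift = shifts,
                 mode = if (all(shifts <= ch_threshold)) "CH" else "other",
                 axis_cell_angle = axis_angle),
            class = "packing_mode")
}

#' @export
print.packing_mode <- function(x, ...) {
  cat(sprintf("Packing: %s mode, successive shift(s) %s A\n", x$mode,
              paste(sprintf("%.2f", x$successive_shift), collapse = ", ")))
  invisible(x)
}

# ---- contacts -------------------------------------------------------------

contact_row <- function(kind, i, j, labels, d_DA = NA, d_HA = NA, angle = NA) {
  data.frame(kind = kind, atom1 = labels[i], atom2 = labels[j],
             idx1 = i, idx2 = j, d_DA = d_DA, d_HA = d_HA,
             angle_DHA = angle, stringsAsFactors = FALSE)
}

empty_contacts <- function() {
  data.frame(kind = character(0), atom1 = character(0), atom2 = character(0),
             idx1 = integer(0), idx2 = integer(0), d_DA = numeric(0),
             d_HA = numeric(0), angle_DHA = numeric(0),
             stringsAsFactors = FALSE)
}

#' Hydrogen-bond detection
#'
#' Pairs O/N donors with O/N acceptors.  A donor-acceptor pair is accepted
#' when `d_DA <= max_da` (inclusive).  When the donor carries a modelled
#' hydrogen the geometric criteria `d_HA <= max_ha` and
#' `angle_DHA >= min_angle` must additionally hold; donors without modelled
#' hydrogens (e.g. water in deposits refined H-free) are screened on
#' `d_DA` alone.  Each unordered pair is reported once.
#'
#' @param structure A [crystal_structure()].
#' @param max_da Donor-acceptor distance cutoff, Angstrom (default 3.4).
#' @param max_ha Hydrogen-acceptor distance cutoff when H is present
#'   (default 2.7).
#' @param min_angle D-H...A angle cutoff in degrees when H is present
#'   (default 120).
#' @param symmetry_mates Also search contacts to symmetry images (all
#'   operators, lattice shifts -1..1); image atoms are tagged in the label.
#' @return A data.frame of contacts (possibly empty): `kind`, `atom1`,
#'   `atom2`, `d_DA`, `d_HA`, `angle_DHA`.
#' @export
find_hbonds <- function(structure, max_da = 3.4, max_ha = 2.7,
                        min_angle = 120, symmetry_mates = FALSE) {
  structure0 <- structure
  if (symmetry_mates && length(structure$symops)) {
    imgs <- list()
    for (op in structure$symops)
      for (sx in -1:1) for (sy in -1:1) for (sz in -1:1) {
        is_id <- isTRUE(all.equal(op$rotation, diag(3))) &&
          all(op$translation_12 == 0) && sx == 0 && sy == 0 && sz == 0
        if (is_id) next
        imgs[[length(imgs) + 1L]] <-
          as_cartesian(expand_symmetry(structure0, op, c(sx, sy, sz)))$atoms
      }
    structure <- as_cartesian(structure0)
    structure$atoms <- do.call(rbind, c(list(structure$atoms), imgs))
    n0 <- nrow(as_cartesian(structure0)$atoms)
  } else {
    structure <- as_cartesian(structure)
    n0 <- nrow(structure$atoms)
  }
  atoms <- structure$atoms
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  el <- toupper(atoms$element)
  don <- which(el %in% c("O", "N"))
  acc <- don
  hyd <- which(el == "H")
  # map each H to its covalent heavy partner (closest within 1.2 A)
  h_owner <- rep(NA_integer_, nrow(atoms))
  for (h in hyd) {
    d <- sqrt(colSums((t(xyz) - xyz[h, ])^2))
    d[h] <- Inf; d[el == "H"] <- Inf
    if (min(d) < 1.25) h_owner[h] <- which.min(d)
  }
  out <- list()
  for (dn in don[don <= n0]) {
    dh <- hyd[!is.na(h_owner[hyd]) & h_owner[hyd] == dn]
    for (ac in acc) {
      if (ac == dn) next
      if (dn > ac && ac <= n0 && !length(dh) &&
          !length(hyd[!is.na(h_owner[hyd]) & h_owner[hyd] == ac]))
        next   # both H-free: dedupe unordered pair
      dda <- vnorm(xyz[ac, ] - xyz[dn, ])
      if (dda > max_da || dda < 0.5) next
      if (length(dh)) {
        best <- NULL
        for (h in dh) {
          dha <- vnorm(xyz[ac, ] - xyz[h, ])
          angle <- vangle(xyz[dn, ] - xyz[h, ], xyz[ac, ] - xyz[h, ])
          if (dha <= max_ha && angle >= min_angle &&
              (is.null(best) || dha < best$d_HA))
            best <- list(d_HA = dha, angle = angle)
        }
        if (!is.null(best))
          out[[length(out) + 1L]] <-
            contact_row("O-H...O", dn, ac, atoms$label, dda, best$d_HA, best$angle)
      } else {
        out[[length(out) + 1L]] <-
          contact_row("O-H...O", dn, ac, atoms$label, dda)
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else empty_contacts()
  dedupe_contacts(res)
}

dedupe_contacts <- function(df) {
  if (!nrow(df)) return(df)
  key <- paste(df$kind, pmin(df$idx1, df$idx2), pmax(df$idx1, df$idx2))
  df[!duplicated(key), , drop = FALSE]
}

#' Close-contact detection (C-H...O and H...H)
#'
#' C-H...O contacts require `d_HA <= chO_max` and C-H...O angle
#' `>= chO_min_angle`; H...H contacts require an H-H separation at or below
#' `hh_max` (twice the hydrogen van der Waals radius).  Hydrogens must be
#' modelled.
#'
#' @param structure A [crystal_structure()].
#' @param kinds Character subset of `c("chO", "hh")`.
#' @param chO_max,chO_min_angle,hh_max Cutoffs (2.9 Angstrom, 110 degrees,
#'   2.4 Angstrom by default).
#' @return A contacts data.frame as in [find_hbonds()].
#' @export
find_close_contacts <- function(structure, kinds = c("chO", "hh"),
                                chO_max = 2.9, chO_min_angle = 110,
                                hh_max = 2.4) {
  structure <- as_cartesian(structure)
  atoms <- structure$atoms
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  el <- toupper(atoms$element)
  hyd <- which(el == "H")
  out <- list()
  h_owner <- rep(NA_integer_, nrow(atoms))
  for (h in hyd) {
    d <- sqrt(colSums((t(xyz) - xyz[h, ])^2))
    d[h] <- Inf; d[el == "H"] <- Inf
    if (min(d) < 1.25) h_owner[h] <- which.min(d)
  }
  if ("chO" %in% kinds) {
    ch <- hyd[!is.na(h_owner[hyd]) & el[h_owner[hyd]] == "C"]
    for (h in ch) for (o in which(el == "O")) {
      dha <- vnorm(xyz[o, ] - xyz[h, ])
      if (dha > chO_max) next
      cidx <- h_owner[h]
      angle <- vangle(xyz[cidx, ] - xyz[h, ], xyz[o, ] - xyz[h, ])
      if (angle >= chO_min_angle)
        out[[length(out) + 1L]] <-
          contact_row("C-H...O", cidx, o, atoms$label,
                      vnorm(xyz[o, ] - xyz[cidx, ]), dha, angle)
    }
  }
  if ("hh" %in% kinds && length(hyd) >= 2) {
    for (a in seq_along(hyd)) for (b in seq_along(hyd)) {
      if (a >= b) next
      i <- hyd[a]; j <- hyd[b]
      if (!is.na(h_owner[i]) && !is.na(h_owner[j]) && h_owner[i] == h_owner[j])
        next   # geminal pair, not a contact
      dhh <- vnorm(xyz[j, ] - xyz[i, ])
      if (dhh <= hh_max)
        out[[length(out) + 1L]] <-
          contact_row("H...H", i, j, atoms$label, d_HA = dhh)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else empty_contacts()
  dedupe_contacts(res)
}
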