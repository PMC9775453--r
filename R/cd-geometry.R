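# Conformational descriptors of the cyclodextrin macrocycle.  All angles in
# degrees, all distances in Angstrom.

#' Least-squares mean plane through a point set
#'
#' The plane minimising the sum of squared orthogonal distances (total least
#' squares, via eigen-decomposition of the point covariance).  Signed
#' deviations sum to zero by construction.
#'
#' @param points An `n x 3` matrix, n >= 3, not collinear.
#' @param orient Optional 3-vector: flip the normal so that
#'   `normal . orient > 0` (used to point the normal toward a host's primary
#'   rim).  Default orientation makes the normal's largest-magnitude
#'   component positive, a deterministic tie-break.
#' @return An object of class `"plane_fit"`: `normal` (unit 3-vector),
#'   `point` (centroid), `rms_dev`, `per_point_dev` (signed, Angstrom).
#' @export
fit_mean_plane <- function(points, orient = NULL) {
  points <- as.matrix(points)
  if (nrow(points) < 3) stop("need at least 3 points to fit a plane")
  ctr <- unname(colMeans(points))
  X <- sweep(points, 2, ctr)
  ev <- eigen(crossprod(X), symmetric = TRUE)
  if (ev$values[2] < 1e-12 * max(ev$values[1], 1))
    stop("degenerate (collinear) point set: no unique mean plane")
  normal <- ev$vectors[, 3]
  if (!is.null(orient)) {
    if (sum(normal * orient) < 0) normal <- -normal
  } else if (normal[which.max(abs(normal))] < 0) normal <- -normal
  dev <- as.numeric(X %*% normal)
  structure(list(normal = normal, point = ctr,
                 rms_dev = sqrt(mean(dev^2)), per_point_dev = dev),
            class = "plane_fit")
}

#' @export
print.plane_fit <- function(x, ...) {
  cat(sprintf("Mean plane: normal (%.4f, %.4f, %.4f), rms deviation %.4f A\n",
              x$normal[1], x$normal[2], x$normal[3], x$rms_dev))
  invisible(x)
}

#' O4 heptagon metrics
#'
#' Regularity descriptors of the seven glycosidic oxygens: distances from
#' their centroid (`d_K`), adjacent O4-O4 distances (`d`, in ring order),
#' signed deviations from the O4 mean plane (`dev`), and the ellipticity
#' `max(d_K)/min(d_K)`.  The centroid is the arithmetic mean of the seven
#' positions.
#'
#' @param host A [cd_host].
#' @return A list of class `"polygon_metrics"` with fields `d_K`, `d`,
#'   `dev`, `ellipticity`, `centroid`, `plane`.
#' @export
o4_polygon_metrics <- function(host) {
  o4 <- host_role_coords(host, "O4")
  ctr <- colMeans(o4)
  d_K <- sqrt(rowSums(sweep(o4, 2, ctr)^2))
  d <- sqrt(rowSums((o4[c(2:7, 1), ] - o4)^2))
  plane <- fit_mean_plane(o4, orient = cd_axis_direction(host))
  structure(list(d_K = d_K, d = d, dev = plane$per_point_dev,
                 ellipticity = max(d_K) / min(d_K),
                 centroid = ctr, plane = plane),
            class = "polygon_metrics")
}

#' @export
print.polygon_metrics <- function(x, ...) {
  cat(sprintf("O4 heptagon: d_K %.3f-%.3f A, d %.3f-%.3f A, |dev| max %.3f A, ellipticity %.3f\n",
              min(x$d_K), max(x$d_K), min(x$d), max(x$d),
              max(abs(x$dev)), x$ellipticity))
  invisible(x)
}

# Unoriented axis estimate used internally before the oriented cd_axis()
# is available (primary-rim direction from the C6/O4 centroids).
cd_axis_direction <- function(host) {
  o4ctr <- colMeans(host_role_coords(host, "O4"))
  prim <- try(colMeans(host_role_coords(host, "C6")), silent = TRUE)
  if (inherits(prim, "try-error"))
    prim <- colMeans(host_role_coords(host, "C5"))
  u <- prim - o4ctr
  if (vnorm(u) < 1e-9) c(0, 0, 1) else unitv(u)
}

#' Approximate sevenfold cavity axis
#'
#' Normal of the O4 best-fit plane anchored at the O4 centroid, oriented
#' from the secondary (O2/O3) rim toward the primary (O6) rim.
#'
#' @param host A [cd_host].
#' @return List with `direction` (unit 3-vector) and `anchor` (O4 centroid).
#' @export
cd_axis <- function(host) {
  o4 <- host_role_coords(host, "O4")
  plane <- fit_mean_plane(o4, orient = cd_axis_direction(host))
  list(direction = plane$normal, anchor = plane$point)
}

#' Glucose tilt angle
#'
#' Angle between the O4 mean plane and the plane through O4(n-1), C1(n),
#' C4(n), O4(n).  The magnitude is the folded interplanar angle; the sign is
#' positive when the residue's primary side (O6 direction) inclines toward
#' the cavity axis, resolved by the dot product of the residue-plane normal
#' (oriented toward the residue's O6/C6 side) with the inward radial
#' direction at the residue's O4.
#'
#' @param host A [cd_host].
#' @param n Residue index 1..7, or `NULL` for all seven.
#' @return Signed angle(s) in degrees.
#' @export
tilt_angle <- function(host, n = NULL) {
  if (is.null(n)) return(vapply(1:7, function(k) tilt_angle(host, k), 0))
  prev <- ((n - 2) %% 7) + 1
  pts <- rbind(host_role_coords(host, "O4", prev),
               host_role_coords(host, "C1", n),
               host_role_coords(host, "C4", n),
               host_role_coords(host, "O4", n))
  o4 <- host_role_coords(host, "O4")
  o4plane <- fit_mean_plane(o4, orient = cd_axis_direction(host))
  # orient the residue-plane normal to the primary (C6/O6) side
  prim_ref <- if ("C6" %in% names(host$residues[[n]]))
    host_role_coords(host, "C6", n) else host_role_coords(host, "C5", n)
  rplane <- fit_mean_plane(pts, orient = prim_ref - colMeans(pts))
  ang <- fold_angle(rplane$normal, o4plane$normal)
  # inward radial direction at O4(n), within the O4 plane
  inward <- o4plane$point - host_role_coords(host, "O4", n)
  inward <- inward - sum(inward * o4plane$normal) * o4plane$normal
  s <- if (sum(rplane$normal * inward) >= 0) 1 else -1
  s * ang
}

#' Primary-rim rotamer state
#'
#' Classifies the exocyclic C5-C6 bond by the torsions
#' omega = O5-C5-C6-O6 and omega' = C4-C5-C6-O6 (IUPAC sign convention).
#' Ideal pairs: gg (-60, +60), gt (+60, 180), tg (180, -60); a state is
#' assigned when both torsions fall within `window` degrees of the ideal
#' pair, else `"unclassified"`.  When alternate disorder sites of the same
#' residue classify differently the summary state is `"both"`.
#'
#' @param host A [cd_host].
#' @param n Residue index 1..7, or `NULL` for all (data.frame).
#' @param window Half-width of the classification window, degrees
#'   (default 30).
#' @return For one residue: list with `omega`, `omega_prime`, `state`.
#'   For all: a 7-row data.frame.
#' @export
rim_torsion_state <- function(host, n = NULL, window = 30) {
  if (is.null(n)) {
    rows <- lapply(1:7, function(k) {
      r <- rim_torsion_state(host, k, window)
      data.frame(residue = k, omega = r$omega, omega_prime = r$omega_prime,
                 state = r$state, stringsAsFactors = FALSE)
    })
    return(do.call(rbind, rows))
  }
  roles <- names(host$residues[[n]])
  if (!all(c("C6", "O6") %in% roles))
    return(list(omega = NA_real_, omega_prime = NA_real_,
                state = "unclassified",
                reason = "O6/C6 not modelled for this residue"))
  o5 <- host_role_coords(host, "O5", n)
  c5 <- host_role_coords(host, "C5", n)
  c6 <- host_role_coords(host, "C6", n)
  o6 <- host_role_coords(host, "O6", n)
  c4 <- host_role_coords(host, "C4", n)
  omega <- dihedral(o5, c5, c6, o6)
  omega_p <- dihedral(c4, c5, c6, o6)
  state <- classify_rotamer(omega, omega_p, window)
  list(omega = omega, omega_prime = omega_p, state = state)
}

classify_rotamer <- function(omega, omega_prime, window = 30) {
  ideal <- list(gg = c(-60, 60), gt = c(60, 180), tg = c(180, -60))
  circ <- function(a, b) {
    d <- abs(a - b) %% 360
    pmin(d, 360 - d)
  }
  for (st in names(ideal))
    if (circ(omega, ideal[[st]][1]) <= window &&
        circ(omega_prime, ideal[[st]][2]) <= window) return(st)
  "unclassified"
}

#' Cremer-Pople ring puckering
#'
#' Puckering amplitude Q and spherical angles (theta, phi) of a
#' six-membered ring given in the order O5-C1-C2-C3-C4-C5.  Under this
#' ordering the standard 4C1 chair of a D-glucopyranose lies at the
#' theta = 0 pole; `is_4C1` is `TRUE` when theta <= `chair_window`.
#'
#' @param ring_coords A `6 x 3` matrix, atoms in the order
#'   O5, C1, C2, C3, C4, C5.
#' @param chair_window Degrees; default 30.
#' @return List of class `"pucker_result"`: `Q` (Angstrom), `theta`, `phi`
#'   (degrees), `is_4C1`.
#' @export
ring_pucker <- function(ring_coords, chair_window = 30) {
  ring_coords <- as.matrix(ring_coords)
  if (nrow(ring_coords) != 6 || ncol(ring_coords) != 3)
    stop("ring_pucker needs exactly 6 atoms (got ", nrow(ring_coords), ")")
  N <- 6
  ctr <- colMeans(ring_coords)
  X <- sweep(ring_coords, 2, ctr)
  j <- seq_len(N) - 1
  R1 <- colSums(X * sin(2 * pi * j / N))
  R2 <- colSums(X * cos(2 * pi * j / N))
  nrm <- unitv(vcross(R1, R2))
  z <- as.numeric(X %*% nrm)
  Q <- sqrt(sum(z^2))
  if (Q < 1e-10)
    return(structure(list(Q = 0, theta = NA_real_, phi = NA_real_,
                          is_4C1 = FALSE), class = "pucker_result"))
  q2c <- sqrt(2 / N) * sum(z * cos(4 * pi * j / N))
  q2s <- -sqrt(2 / N) * sum(z * sin(4 * pi * j / N))
  q2 <- sqrt(q2c^2 + q2s^2)
  q3 <- sqrt(1 / N) * sum(z * (-1)^j)
  theta <- atan2(q2, q3) * 180 / pi
  phi <- (atan2(q2s, q2c) * 180 / pi) %% 360
  structure(list(Q = Q, theta = theta, phi = phi,
                 is_4C1 = theta <= chair_window),
            class = "pucker_result")
}

#' @export
print.pucker_result <- function(x, ...) {
  cat(sprintf("Cremer-Pople: Q = %.3f A, theta = %.1f deg, phi = %.1f deg (%s)\n",
              x$Q, x$theta, x$phi, if (isTRUE(x$is_4C1)) "4C1 chair" else "not 4C1"))
  invisible(x)
}

#' Puckering of one glucose residue of a host
#'
#' @param host A [cd_host].
#' @param n Residue index 1..7.
#' @inheritParams ring_pucker
#' @export
residue_pucker <- function(host, n, chair_window = 30) {
  ring <- t(vapply(c("O5", "C1", "C2", "C3", "C4", "C5"),
                   function(r) host_role_coords(host, r, n), numeric(3)))
  ring_pucker(ring, chair_window)
}

#' Per-residue descriptor table for a host
#'
#' One row per glucose residue: heptagon metrics, tilt, rim torsions and
#' rotamer state, and ring puckering — the standard one-glance summary of a
#' macrocycle conformation.
#'
#' @param host A [cd_host].
#' @return A 7-row data.frame.
#' @export
cd_geometry_summary <- function(host) {
  pm <- o4_polygon_metrics(host)
  tau <- tilt_angle(host)
  rim <- rim_torsion_state(host)
  pk <- lapply(1:7, function(n) residue_pucker(host, n))
  data.frame(residue = 1:7,
             d_K = pm$d_K, d = pm$d, dev = pm$dev,
             tau = tau,
             omega = rim$omega, omega_prime = rim$omega_prime,
             state = rim$state,
             Q = vapply(pk, `[[`, 0, "Q"),
             theta = vapply(pk, `[[`, 0, "theta"),
             is_4C1 = vapply(pk, `[[`, TRUE, "is_4C1"),
             stringsAsFactors = FALSE)
}
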