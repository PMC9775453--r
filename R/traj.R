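# Time-series geometric analysis: Kabsch superposition, RMSD to a reference
# frame, interatomic distance monitoring, per-frame hydrogen-bond counts.

#' Kabsch superposition
#'
#' Least-squares rigid superposition of `mobile` onto `reference` over a
#' selection.  Returns the proper rotation (det = +1) and translation that
#' minimise the RMSD of the selected atoms, with the attained RMSD.
#'
#' @param reference,mobile `n x 3` coordinate matrices with matching rows.
#' @param selection Integer indices used for the fit (default: all rows).
#' @return List: `rotation` (3 x 3), `translation` (length 3), `rmsd`
#'   (Angstrom, over the selection).  The fitted mobile coordinates are
#'   `mobile %*% t(rotation) + translation` (row-wise).
#' @export
kabsch_superpose <- function(reference, mobile, selection = NULL) {
  reference <- as.matrix(reference); mobile <- as.matrix(mobile)
  if (!all(dim(reference) == dim(mobile)))
    stop("reference and mobile must have identical dimensions")
  if (is.null(selection)) selection <- seq_len(nrow(reference))
  if (length(selection) < 3)
    stop("need at least 3 atoms in the fit selection")
  P <- mobile[selection, , drop = FALSE]
  Q <- reference[selection, , drop = FALSE]
  pc <- colMeans(P); qc <- colMeans(Q)
  P0 <- sweep(P, 2, pc); Q0 <- sweep(Q, 2, qc)
  if (sum(svd(crossprod(P0))$d > 1e-10 * max(1, sum(P0^2))) < 2)
    stop("degenerate (collinear) fit selection")
  H <- crossprod(P0, Q0)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- qc - as.numeric(R %*% pc)
  fitted <- sweep(P %*% t(R), 2, t, `+`)
  list(rotation = R, translation = t,
       rmsd = sqrt(mean(rowSums((fitted - Q)^2))))
}

apply_fit <- function(xyz, fit) sweep(xyz %*% t(fit$rotation), 2, fit$translation, `+`)

#' RMSD time series relative to a reference frame
#'
#' Each frame is superposed on the reference over `fit_selection`
#' (fit-then-measure convention), then the RMSD is evaluated over
#' `measure_selection`.  Separate selections support the common pattern of
#' fitting on the host and measuring guest displacement.
#'
#' @param traj A [trajectory()].
#' @param measure_selection,fit_selection Integer atom indices; default all
#'   atoms for both.
#' @param reference Reference frame index (default 1, the first frame).
#' @param mass_weight Optional per-atom weights for the measured RMSD
#'   (default none).
#' @return Object of class `"rmsd_series"`: numeric `values` (Angstrom, one
#'   per frame; 0 at the reference), plus the selections used.
#' @export
rmsd_series <- function(traj, measure_selection = NULL, fit_selection = NULL,
                        reference = 1, mass_weight = NULL) {
  nat <- dim(traj$coords)[1]
  if (is.null(measure_selection)) measure_selection <- seq_len(nat)
  if (is.null(fit_selection)) fit_selection <- seq_len(nat)
  if (!length(measure_selection)) stop("empty measure selection")
  if (any(c(measure_selection, fit_selection) > nat) ||
      any(c(measure_selection, fit_selection) < 1))
    stop("selection index out of range")
  ref <- frame_coords(traj, reference)
  w <- if (is.null(mass_weight)) rep(1, length(measure_selection)) else
    mass_weight[measure_selection]
  vals <- vapply(seq_len(n_frames(traj)), function(k) {
    xyz <- frame_coords(traj, k)
    fit <- kabsch_superpose(ref, xyz, fit_selection)
    moved <- apply_fit(xyz, fit)
    dd <- rowSums((moved[measure_selection, , drop = FALSE] -
                     ref[measure_selection, , drop = FALSE])^2)
    sqrt(sum(w * dd) / sum(w))
  }, numeric(1))
  structure(list(values = vals, measure_selection = measure_selection,
                 fit_selection = fit_selection, reference = reference,
                 timestep = traj$timestep),
            class = "rmsd_series")
}

#' @export
print.rmsd_series <- function(x, ...) {
  cat(sprintf("RMSD series: %d frames, mean %.3f A, max %.3f A (reference frame %d)\n",
              length(x$values), mean(x$values), max(x$values), x$reference))
  invisible(x)
}

#' @export
plot.rmsd_series <- function(x, ...) {
  t <- (seq_along(x$values) - 1) * x$timestep
  graphics::plot(t, x$values, type = "l", xlab = "time (ps)",
                 ylab = "RMSD (A)", ...)
  invisible(x)
}

#' Interatomic distance time series
#'
#' Per-frame Euclidean distances for a set of atom pairs, with an optional
#' contact fraction (share of frames at or below a cutoff).
#'
#' @param traj A [trajectory()].
#' @param pairs Two-column integer matrix (or length-2 vector) of atom
#'   index pairs.
#' @param contact_cutoff Optional cutoff (Angstrom) for the contact
#'   fraction.
#' @return A list of class `"distance_series"`: `values` (frames x pairs
#'   matrix), `pairs`, and `contact_fraction` (per pair, or `NULL`).
#' @export
distance_series <- function(traj, pairs, contact_cutoff = NULL) {
  if (is.null(dim(pairs))) pairs <- matrix(pairs, ncol = 2)
  nat <- dim(traj$coords)[1]
  if (any(pairs < 1) || any(pairs > nat))
    stop("atom index out of range in pairs")
  vals <- vapply(seq_len(n_frames(traj)), function(k) {
    xyz <- frame_coords(traj, k)
    sqrt(rowSums((xyz[pairs[, 1], , drop = FALSE] -
                    xyz[pairs[, 2], , drop = FALSE])^2))
  }, numeric(nrow(pairs)))
  vals <- if (nrow(pairs) == 1) matrix(vals, ncol = 1) else t(vals)
  cf <- if (is.null(contact_cutoff)) NULL else colMeans(vals <= contact_cutoff)
  structure(list(values = vals, pairs = pairs, contact_fraction = cf,
                 timestep = traj$timestep),
            class = "distance_series")
}

#' @export
print.distance_series <- function(x, ...) {
  cat(sprintf("Distance series: %d pair(s) x %d frames; means %s A\n",
              ncol(x$values), nrow(x$values),
              paste(sprintf("%.2f", colMeans(x$values)), collapse = ", ")))
  invisible(x)
}

#' Per-frame hydrogen-bond counts
#'
#' Counts donor-H...acceptor geometries meeting MD-style criteria
#' (`d_DA <= max_da`, `angle_DHA >= min_angle`; defaults 3.5 Angstrom and
#' 135 degrees) in every frame, with a running mean over a window.
#'
#' @param traj A [trajectory()].
#' @param donors Two-column integer matrix: donor heavy-atom index,
#'   attached hydrogen index.
#' @param acceptors Integer vector of acceptor heavy-atom indices.
#' @param max_da,min_angle Geometric criteria.
#' @param window Running-average window in frames (default 100, truncated
#'   at the series length).
#' @return Object of class `"hbond_series"`: integer `counts` per frame and
#'   `window_mean`.
#' @export
hbond_count_series <- function(traj, donors, acceptors, max_da = 3.5,
                               min_angle = 135, window = 100) {
  if (is.null(dim(donors))) donors <- matrix(donors, ncol = 2)
  counts <- vapply(seq_len(n_frames(traj)), function(k) {
    xyz <- frame_coords(traj, k)
    n <- 0L
    for (r in seq_len(nrow(donors))) {
      d <- donors[r, 1]; h <- donors[r, 2]
      for (a in acceptors) {
        if (a == d) next
        if (vnorm(xyz[a, ] - xyz[d, ]) > max_da) next
        ang <- vangle(xyz[d, ] - xyz[h, ], xyz[a, ] - xyz[h, ])
        if (ang >= min_angle) n <- n + 1L
      }
    }
    n
  }, integer(1))
  w <- max(1L, min(as.integer(window), length(counts)))
  wm <- stats::filter(counts, rep(1 / w, w), sides = 2)
  structure(list(counts = counts, window_mean = as.numeric(wm),
                 window = w, timestep = traj$timestep),
            class = "hbond_series")
}

#' @export
print.hbond_series <- function(x, ...) {
  cat(sprintf("H-bond counts: %d frames, mean %.2f, range %d-%d\n",
              length(x$counts), mean(x$counts), min(x$counts), max(x$counts)))
  invisible(x)
}
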