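# Independent oracles and small fixture builders used across the suite.

# Brute-force total-least-squares plane: coarse-to-fine grid search over
# unit normals, refined to ~0.002 degrees.  Independent of the
# eigen-decomposition route used by fit_mean_plane().
oracle_plane_normal <- function(points) {
  points <- as.matrix(points)
  ctr <- colMeans(points)
  X <- sweep(points, 2, ctr)
  sse <- function(n) sum((X %*% n)^2)
  # coarse sweep over the half-sphere
  best <- c(0, 0, 1); best_sse <- sse(best)
  for (th in seq(0, 90, by = 4) * pi / 180)
    for (ph in seq(0, 356, by = 4) * pi / 180) {
      n <- c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
      s <- sse(n)
      if (s < best_sse) { best_sse <- s; best <- n }
    }
  # tangent-plane refinement, halving the search window each round
  h <- 0.03
  for (refine in 1:24) {
    ref <- if (abs(best[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    u <- ref - sum(ref * best) * best; u <- u / sqrt(sum(u^2))
    v <- c(best[2] * u[3] - best[3] * u[2],
           best[3] * u[1] - best[1] * u[3],
           best[1] * u[2] - best[2] * u[1])
    for (a in seq(-3, 3) * h) for (b in seq(-3, 3) * h) {
      n <- best + a * u + b * v
      n <- n / sqrt(sum(n^2))
      s <- sse(n)
      if (s < best_sse) { best_sse <- s; best <- n }
    }
    h <- h / 2
  }
  list(normal = best, rms = sqrt(best_sse / nrow(points)))
}

# Coarse rotation-space search (axis-angle grid) for the best rigid
# superposition RMSD; used to confirm Kabsch optimality from an
# independent direction.
oracle_best_rmsd <- function(reference, mobile, n_axis = 200, n_angle = 72) {
  ref0 <- sweep(reference, 2, colMeans(reference))
  mob0 <- sweep(mobile, 2, colMeans(mobile))
  set.seed(42)
  axes <- matrix(rnorm(3 * n_axis), n_axis, 3)
  axes <- axes / sqrt(rowSums(axes^2))
  best <- Inf
  for (i in seq_len(n_axis)) for (ang in seq(0, 355, length.out = n_angle)) {
    R <- cycloscope:::rotation_about(axes[i, ], ang)
    r <- sqrt(mean(rowSums((mob0 %*% t(R) - ref0)^2)))
    if (r < best) best <- r
  }
  best
}

random_unit_cell <- function() {
  repeat {
    cell <- try(unit_cell(runif(1, 5, 30), runif(1, 5, 30), runif(1, 5, 30),
                          runif(1, 60, 120), runif(1, 60, 120),
                          runif(1, 60, 120)), silent = TRUE)
    if (!inherits(cell, "try-error")) return(cell)
  }
}

# a minimal small-molecule CIF on disk; returns the path
write_tiny_cif <- function(path = tempfile(fileext = ".cif")) {
  writeLines(c(
    "data_tiny",
    "_cell_length_a 10.0", "_cell_length_b 10.0", "_cell_length_c 10.0",
    "_cell_angle_alpha 90", "_cell_angle_beta 90", "_cell_angle_gamma 90",
    "_symmetry_space_group_name_H-M 'P 21'",
    "loop_",
    "_symmetry_equiv_pos_as_xyz",
    "x,y,z",
    "-x,y+1/2,-z",
    "loop_",
    "_atom_site_label", "_atom_site_type_symbol",
    "_atom_site_fract_x", "_atom_site_fract_y", "_atom_site_fract_z",
    "_atom_site_occupancy",
    "O1 O 0.5 0.5 0.5 1.0"), path)
  path
}

write_tiny_pdb <- function(path = tempfile(fileext = ".pdb")) {
  fmt <- function(serial, name, resno, x, y, z)
    sprintf("ATOM  %5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            serial, name, "HOH", "A", resno, x, y, z, 1, 0, "O")
  writeLines(c(fmt(1, " O1 ", 1, 0, 0, 0),
               fmt(2, " O2 ", 2, 3, 0, 0),
               fmt(3, " O3 ", 3, 0, 4, 0),
               "END"), path)
  path
}

# simple structure from a coordinate matrix
structure_from_xyz <- function(xyz, elements = rep("C", nrow(xyz))) {
  crystal_structure(data.frame(label = paste0(elements, seq_len(nrow(xyz))),
                               element = elements,
                               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                               stringsAsFactors = FALSE))
}

expect_equal_tol <- function(object, expected, tol) {
  expect_true(all(abs(object - expected) <= tol),
              label = sprintf("max deviation %.3g within %.3g",
                              max(abs(object - expected)), tol))
}

# circular comparison for torsion angles (180 and -180 are the same angle)
expect_equal_circ <- function(object, expected, tol) {
  d <- abs(object - expected) %% 360
  d <- pmin(d, 360 - d)
  expect_true(all(d <= tol),
              label = sprintf("max circular deviation %.3g within %.3g",
                              max(d), tol))
}
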