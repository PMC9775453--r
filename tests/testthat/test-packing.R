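# Host-pair and guest arrangement, packing mode, contact detection.

build_pair <- function(orientation, shift = 8, lateral = 0, angle = 0,
                       tilt = 0) {
  build_complex(complex_build_spec(
    hosts = list(cd_build_spec(tilt = tilt), cd_build_spec(tilt = tilt)),
    orientations = orientation, axial_shift = shift,
    lateral_offset = lateral, interplanar_angle = angle, guest = FALSE))
}

test_that("host pair geometry reproduces constructed stacks", {
  cx <- build_pair("head-to-tail", shift = 8)
  hp <- host_pair_geometry(annotate_cd(cx$structure)[[1]],
                           annotate_cd(cx$structure)[[2]])
  expect_equal(hp$interplanar_angle, 0, tolerance = 1e-6)
  expect_equal(hp$axial_shift, 8, tolerance = 1e-9)
  expect_equal(hp$lateral_offset, 0, tolerance = 1e-9)
  expect_identical(hp$orientation, "head-to-tail")

  tt <- build_pair("tail-to-tail")
  hp2 <- host_pair_geometry(annotate_cd(tt$structure)[[1]],
                            annotate_cd(tt$structure)[[2]])
  expect_identical(hp2$orientation, "tail-to-tail")

  hh <- build_pair("head-to-head")
  hp3 <- host_pair_geometry(annotate_cd(hh$structure)[[1]],
                            annotate_cd(hh$structure)[[2]])
  expect_identical(hp3$orientation, "head-to-head")

  # lateral offset and interplanar angle are reproduced
  off <- build_pair("head-to-tail", shift = 8, lateral = 2)
  hp4 <- host_pair_geometry(annotate_cd(off$structure)[[1]],
                            annotate_cd(off$structure)[[2]])
  expect_equal(hp4$lateral_offset, 2, tolerance = 0.05)
  expect_equal(hp4$axial_shift, 8, tolerance = 0.05)
  expect_equal(hp4$centroid_distance^2,
               hp4$lateral_offset^2 + hp4$axial_shift^2, tolerance = 1e-6)
  ang <- build_pair("head-to-tail", angle = 3)
  hp5 <- host_pair_geometry(annotate_cd(ang$structure)[[1]],
                            annotate_cd(ang$structure)[[2]])
  expect_equal(hp5$interplanar_angle, 3, tolerance = 0.01)
})

test_that("host pair geometry is symmetric in its arguments", {
  cx <- build_pair("tail-to-tail", shift = 7.5, lateral = 1)
  a <- annotate_cd(cx$structure)[[1]]
  b <- annotate_cd(cx$structure)[[2]]
  ab <- host_pair_geometry(a, b); ba <- host_pair_geometry(b, a)
  expect_equal(ab$interplanar_angle, ba$interplanar_angle, tolerance = 1e-9)
  expect_equal(ab$centroid_distance, ba$centroid_distance, tolerance = 1e-9)
  expect_equal(ab$axial_shift, ba$axial_shift, tolerance = 1e-9)
  expect_equal(ab$lateral_offset, ba$lateral_offset, tolerance = 1e-9)
  expect_identical(ab$orientation, ba$orientation)
})

test_that("guest ring orientation reproduces constructed placements", {
  # parallel ring on the O4 plane
  cx <- build_complex(complex_build_spec(guest_depth = 0, guest_angle = 0))
  h <- annotate_cd(cx$structure)[[1]]
  ringA <- coords(cx$structure)[cx$truth$guest$ringA, ]
  go <- guest_orientation(ringA, h)
  expect_equal(go$ring_plane_angle, 0, tolerance = 1e-6)
  expect_equal(go$penetration_depth, 0, tolerance = 1e-9)

  # perpendicular ring, 2 A toward the primary rim
  cx2 <- build_complex(complex_build_spec(guest_depth = 2, guest_angle = 90))
  h2 <- annotate_cd(cx2$structure)[[1]]
  go2 <- guest_orientation(coords(cx2$structure)[cx2$truth$guest$ringA, ], h2)
  expect_equal(go2$ring_plane_angle, 90, tolerance = 1e-6)
  expect_equal(go2$penetration_depth, 2, tolerance = 1e-9)

  # oblique placement, the angle the deposits show for threaded guests
  cx3 <- build_complex(complex_build_spec(guest_depth = 1, guest_angle = 70.8))
  h3 <- annotate_cd(cx3$structure)[[1]]
  go3 <- guest_orientation(coords(cx3$structure)[cx3$truth$guest$ringA, ], h3)
  expect_equal(go3$ring_plane_angle, 70.8, tolerance = 0.1)

  th <- pi / 3 * (0:5)
  buckled <- cbind(1.4 * cos(th), 1.4 * sin(th), 0.5 * (-1)^(1:6))
  expect_warning(guest_orientation(buckled, h), "planarity")
})

test_that("packing mode separates channel stacks from shifted ones", {
  base <- coords(build_ideal_cd(cd_build_spec())$structure)
  stack <- function(offsets)
    lapply(offsets, function(o) sweep(base, 2, o, `+`))
  # coaxial: zero shift, channel mode
  pm <- packing_mode(stack(list(c(0, 0, 0), c(0, 0, 8), c(0, 0, 16))),
                     stacking_axis = c(0, 0, 1))
  expect_equal(max(pm$successive_shift), 0, tolerance = 1e-9)
  expect_identical(pm$mode, "CH")
  # 3.0 A constructed offset stays within the channel window
  pm2 <- packing_mode(stack(list(c(0, 0, 0), c(3, 0, 8))),
                      stacking_axis = c(0, 0, 1))
  expect_equal(pm2$successive_shift, 3, tolerance = 1e-9)
  expect_identical(pm2$mode, "CH")
  # 6.0 A offset does not
  pm3 <- packing_mode(stack(list(c(0, 0, 0), c(6, 0, 8))),
                      stacking_axis = c(0, 0, 1))
  expect_identical(pm3$mode, "other")
  expect_error(packing_mode(stack(list(c(0, 0, 0))), c(0, 0, 1)), "2 stacked")
})

test_that("hydrogen bonds follow the distance/angle criteria", {
  # ideal O-H...O at 2.8 A, angle 180
  st <- structure_from_xyz(rbind(c(0, 0, 0), c(0.96, 0, 0), c(2.8, 0, 0)),
                           c("O", "H", "O"))
  hb <- find_hbonds(st)
  expect_equal(nrow(hb), 1)
  expect_equal(hb$d_DA, 2.8, tolerance = 1e-9)
  expect_equal(hb$angle_DHA, 180, tolerance = 1e-6)

  # beyond the cutoff: nothing
  far <- structure_from_xyz(rbind(c(0, 0, 0), c(4, 0, 0)), c("O", "O"))
  expect_equal(nrow(find_hbonds(far)), 0)

  # the 3.4 A boundary is inclusive, and works donor-H-free
  edge <- structure_from_xyz(rbind(c(0, 0, 0), c(3.4, 0, 0)), c("O", "O"))
  expect_equal(nrow(find_hbonds(edge)), 1)

  # a bent D-H...A below the angle cutoff is rejected (both oxygens carry
  # modelled hydrogens, so neither qualifies through the H-free fallback)
  bent <- structure_from_xyz(rbind(c(0, 0, 0), c(0.96, 0, 0),
                                   c(0.5, 2.6, 0), c(0.5, 3.56, 0)),
                             c("O", "H", "O", "H"))
  expect_equal(nrow(find_hbonds(bent)), 0)
})

test_that("close contacts: C-H...O and H...H cutoffs", {
  # constructed C-H...O with d(H...O) = 2.5 A, angle 150
  h <- c(1.09, 0, 0)
  o <- h + 2.5 * c(cos(pi * 30 / 180), sin(pi * 30 / 180), 0)
  st <- structure_from_xyz(rbind(c(0, 0, 0), h, o), c("C", "H", "O"))
  cc <- find_close_contacts(st)
  expect_equal(nrow(cc), 1)
  expect_identical(cc$kind, "C-H...O")
  expect_equal(cc$d_HA, 2.5, tolerance = 1e-9)
  expect_equal(cc$angle_DHA, 150, tolerance = 1e-6)

  # H...H at 2.2 reported, at 2.6 not
  hh <- structure_from_xyz(rbind(c(0, 0, 0), c(1.09, 0, 0),
                                 c(1.09 + 2.2, 0, 0), c(2.2 + 2.18, 0, 0)),
                           c("C", "H", "H", "C"))
  got <- find_close_contacts(hh, kinds = "hh")
  expect_equal(nrow(got), 1)
  expect_equal(got$d_HA, 2.2, tolerance = 1e-9)
  hh2 <- structure_from_xyz(rbind(c(0, 0, 0), c(1.09, 0, 0),
                                  c(1.09 + 2.6, 0, 0), c(2.6 + 2.18, 0, 0)),
                            c("C", "H", "H", "C"))
  expect_equal(nrow(find_close_contacts(hh2, kinds = "hh")), 0)
})

test_that("contact lists report each unordered pair once", {
  set.seed(3)
  xyz <- matrix(runif(60, 0, 6), 20, 3)
  st <- structure_from_xyz(xyz, rep(c("O", "H"), 10))
  for (df in list(find_hbonds(st), find_close_contacts(st))) {
    if (!nrow(df)) next
    key <- paste(pmin(df$idx1, df$idx2), pmax(df$idx1, df$idx2))
    expect_false(any(duplicated(key)))
  }
})

test_that("pair and guest descriptors are invariant under rigid motion", {
  cx <- build_complex(complex_build_spec(
    hosts = list(cd_build_spec(), cd_build_spec()),
    orientations = "tail-to-tail", axial_shift = 9, lateral_offset = 1,
    guest = TRUE, guest_depth = 1, guest_angle = 40))
  hosts <- annotate_cd(cx$structure)
  ref_hp <- host_pair_geometry(hosts[[1]], hosts[[2]])
  ref_go <- guest_orientation(coords(cx$structure)[cx$truth$guest$ringA, ],
                              hosts[[1]])
  set.seed(99)
  for (i in 1:50) {
    R <- cycloscope:::random_rotation()
    moved <- transform_structure(cx$structure, R, rnorm(3, 0, 15))
    mh <- annotate_cd(moved)
    hp <- host_pair_geometry(mh[[1]], mh[[2]])
    go <- guest_orientation(coords(moved)[cx$truth$guest$ringA, ], mh[[1]])
    expect_equal_tol(hp$interplanar_angle, ref_hp$interplanar_angle, 1e-6)
    expect_equal_tol(hp$centroid_distance, ref_hp$centroid_distance, 1e-9)
    expect_equal_tol(hp$axial_shift, ref_hp$axial_shift, 1e-9)
    expect_equal_tol(hp$lateral_offset, ref_hp$lateral_offset, 1e-9)
    expect_identical(hp$orientation, ref_hp$orientation)
    expect_equal_tol(go$ring_plane_angle, ref_go$ring_plane_angle, 1e-6)
    expect_equal_tol(go$penetration_depth, ref_go$penetration_depth, 1e-9)
  }
})
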