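test_that("matching energy is zero for identity and kinetic for isometries", {
  v <- make_stenosis_model(plaque_spec("fibrous", 0.626), n_rings = 41L)
  m <- build_structured_mesh(v$lumen, L = 41L, C = 12L)
  expect_lt(matching_energy(m, m), 1e-10)

  # translation: deformation term vanishes, kinetic term is ||t||^2/d_nom^2
  tr <- c(0.4, -0.3, 0.5)
  mt <- rigid_transform_mesh(m, t = tr)
  d_nom <- 2 * mean(m$radius)
  expect_equal(matching_energy(m, mt, weights = c(0, 1)),
               sum(tr^2) / d_nom^2, tolerance = 1e-9)
  expect_lt(matching_energy(m, mt, weights = c(1, 0)), 1e-9)

  # rotating the mesh one node spacing about its (z) axis: the shifted
  # matching beats identity (brute force over all circumferential offsets)
  rotated <- rigid_transform_mesh(m, rot3(c(0, 0, 1), -2 * pi / 12))
  energies <- vapply(0:11, function(j)
    matching_energy(m, rotated,
                    list(axial_offset = 0,
                         circumferential_offset = j * 2 * pi / 12)), 0)
  expect_lt(energies[2L], energies[1L])
  expect_equal(which.min(energies), 2L)

  small <- build_structured_mesh(straight_frame(), L = 11L, C = 8L)
  expect_error(matching_energy(m, small), "identical node dimensions")
})

test_that("rigid motions and uniform inflation are recovered exactly", {
  # bent tube: no axial or rotational symmetry, so the minimum is unique
  bf <- bent_frame()
  m <- build_structured_mesh(bf, L = 31L, C = 12L)

  R <- rot3(c(1, 2, 3), 0.3); tr <- c(2, -1, 3)
  mb <- rigid_transform_mesh(m, R, tr)
  fld <- map_displacements(m, mb)
  truth <- mb$nodes - m$nodes
  expect_lt(max(abs(fld$vectors - truth)), 1e-8)
  expect_equal(fld$matching$axial_offset, 0)
  expect_equal(fld$matching$circumferential_offset, 0)

  # 12% uniform inflation: identity matching, purely radial displacement
  mi <- m
  mi$nodes <- inflate_grid(m$nodes, 1.12)
  mi$radius <- 1.12 * m$radius
  fi <- map_displacements(m, mi)
  ctr <- mesh_centerline(m)
  radial <- sqrt((m$nodes[, , 1L] - ctr[, 1L])^2 +
                   (m$nodes[, , 2L] - ctr[, 2L])^2 +
                   (m$nodes[, , 3L] - ctr[, 3L])^2)
  mag <- sqrt(fi$vectors[, , 1L]^2 + fi$vectors[, , 2L]^2 + fi$vectors[, , 3L]^2)
  expect_lt(max(abs(mag - 0.12 * radial)), 1e-8)
  # displacement is radial: no axial component for a straight-ish ring frame
  expect_equal(fi$matching$axial_offset, 0)
})

test_that("the discrete search stage agrees with exhaustive enumeration", {
  bf <- bent_frame(n = 13L, length = 12)
  m <- build_structured_mesh(bf, L = 10L, C = 10L)
  # deform: mild inflation plus a two-node circumferential relabelling
  def <- m
  def$nodes <- inflate_grid(m$nodes, 1.05)[, c(3:10, 1:2), , drop = FALSE]
  def$radius <- 1.05 * m$radius

  fld <- map_displacements(m, def, search = list(refine = FALSE))
  spacing <- mean(diff(m$arclength))
  a_offs <- seq(-2, 2, length.out = 5L) * spacing
  grid <- expand.grid(delta = 0:9, a = a_offs)
  grid$e <- mapply(function(d, a)
    matching_energy(m, def, list(axial_offset = a,
                                 circumferential_offset = d * 2 * pi / 10),
                    weights = c(1, 1e-3)),
    grid$delta, grid$a)
  best <- grid[which.min(grid$e), ]
  expect_equal(best$delta, 8)  # undoes the two-node relabelling
  expect_equal(fld$matching$circumferential_offset, best$delta * 2 * pi / 10,
               tolerance = 1e-9)
  expect_equal(fld$matching$axial_offset, best$a, tolerance = 1e-9)
  expect_equal(fld$energy, min(grid$e), tolerance = 1e-12)
})

test_that("forward and backward mappings are opposite for small deformations", {
  bf <- bent_frame()
  m <- build_structured_mesh(bf, L = 31L, C = 12L)
  mi <- m
  mi$nodes <- inflate_grid(m$nodes, 1.05)
  mi$radius <- 1.05 * m$radius
  fwd <- map_displacements(m, mi)
  bwd <- map_displacements(mi, m)
  expect_lt(max(abs(fwd$vectors + bwd$vectors)), 1e-6)
})

test_that("cycle propagation composes mappings and reports closure", {
  v <- make_stenosis_model(plaque_spec("fibrous", 0.626), n_rings = 41L)

  # null motion: every field is zero
  null_mo <- motion_spec(diameter_pulsation = 0, axial_stretch = 0,
                         bending_amplitude = 0, rigid_translation = c(0, 0, 0),
                         rigid_rotation = 0)
  sq0 <- generate_cardiac_sequence(v, null_mo, L = 41L, C = 12L)
  pr0 <- propagate_cycle(sq0)
  expect_lt(max(vapply(pr0$fields, function(f) max(abs(f$vectors)), 0)), 1e-9)
  expect_lt(pr0$closure_residual, 1e-9)

  # pure rigid motion (rotation about y commutes with the mesh construction):
  # isometries compose exactly, closure <= 1e-8
  rig <- motion_spec(diameter_pulsation = 0, axial_stretch = 0,
                     bending_amplitude = 0, rigid_translation = c(1.5, -1, 2),
                     rigid_rotation = 0.04, rotation_axis = c(0, 1, 0))
  sqr <- generate_cardiac_sequence(v, rig, L = 41L, C = 12L)
  prr <- propagate_cycle(sqr)
  expect_lt(prr$closure_residual, 1e-8)
  for (k in 2:5) {
    gt <- sqr$ground_truth$node_grids[[k]]
    expect_lt(max(abs(prr$grids[[k]] - gt)), 1e-8)
  }

  # full synthetic motion: composed correspondence tracks the stored ground
  # truth within 2% of the nominal diameter (RMS)
  sq <- generate_cardiac_sequence(v, motion_spec(), L = 41L, C = 12L)
  pr <- propagate_cycle(sq)
  d_nom <- 2 * mean(pr$diastasis_mesh$radius)
  for (k in 2:5) {
    err <- sqrt(mean(rowSums(matrix(pr$grids[[k]] -
                                      sq$ground_truth$node_grids[[k]],
                                    ncol = 3L)^2)))
    expect_lt(err, 0.02 * d_nom)
  }

  expect_error(propagate_cycle(sq$frames[2:5]), "diastasis")
})

test_that("held-out frames are predicted by time interpolation of the cycle", {
  v <- make_stenosis_model(plaque_spec("fibrous", 0.626), n_rings = 41L)

  # null motion: the prediction is the diastasis centerline itself
  null_mo <- motion_spec(diameter_pulsation = 0, axial_stretch = 0,
                         bending_amplitude = 0, rigid_translation = c(0, 0, 0),
                         rigid_rotation = 0)
  sq0 <- generate_cardiac_sequence(v, null_mo, L = 41L, C = 12L)
  p0 <- predict_frame(sq0, 3L)
  expect_lt(max(abs(p0$centerline$points -
                      mesh_centerline(build_structured_mesh(sq0$frames[[1L]],
                                                            41L, 12L)))), 1e-9)

  # translation linear in time: interpolation is exact
  lin <- motion_spec(diameter_pulsation = 0, axial_stretch = 0,
                     bending_amplitude = 0, rigid_translation = c(1, 2, 0.5),
                     rigid_rotation = 0,
                     phase_weights = c(diastasis = 0, end_diastole = 0.25,
                                       early_systole = 0.5, end_systole = 0.75,
                                       early_diastole = 1))
  sql <- generate_cardiac_sequence(v, lin, L = 41L, C = 12L)
  pl <- predict_frame(sql, 3L)
  truth <- mesh_centerline(build_structured_mesh(sql$frames[[3L]], 41L, 12L))
  expect_lt(max(abs(pl$centerline$points - truth)), 1e-9)

  expect_error(predict_frame(sql, 1L), "diastasis")
  short <- sql; short$frames <- sql$frames[1:3]
  expect_error(predict_frame(short, 2L), "at least 3")
})
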