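test_that("daughter diameter follows the symmetric cube law", {
  expect_equal(round(daughter_diameter(10), 2), 7.94)
  expect_equal(daughter_diameter(2^(1 / 3)), 1.0, tolerance = 1e-12)
  expect_equal(daughter_diameter(20), 20 * 2^(-1 / 3), tolerance = 1e-12)
  # cube law holds exactly, the area law does not
  D1 <- daughter_diameter(10)
  expect_equal(2 * D1^3, 10^3, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(2 * (D1 / 2)^2, (10 / 2)^2)))
  expect_error(daughter_diameter(0), "positive")
  expect_error(daughter_diameter(-3), "positive")
})

test_that("geometry construction places the bifurcation and rejects bad probes", {
  geom <- build_geometry(bifurcation_params(), list())
  expect_equal(geom$centerlines$root[2, ], c(0, 0, -20))
  # phi -> 0 degenerates to a straight tube along the axis
  g0 <- build_geometry(bifurcation_params(phi = 1e-6), list())
  expect_lt(max(abs(g0$centerlines$daughter_pos[, 1])), 1e-6)
  expect_equal(g0$centerlines$daughter_pos[nrow(g0$centerlines$daughter_pos), 3],
               -100, tolerance = 1e-6)
  # a probe driven into the lumen is a placement error
  expect_error(build_geometry(bifurcation_params(),
                              probe_spec(Ld = 0, Dp = 4)),
               "placement error")
  # a probe outside the tissue cylinder is a placement error
  expect_error(build_geometry(bifurcation_params(),
                              probe_spec(tip_center = c(70, 0, -50))),
               "placement error")
  # sub-tolerance grazing contact warns instead of failing
  expect_warning(build_geometry(bifurcation_params(), probe_spec(Ld = 6)),
                 "grazes")
  # the tightest published placement (Ld = 10 mm) is admissible
  expect_silent(build_geometry(bifurcation_params(), probe_spec(Ld = 10)))
})

test_that("voxelized label volumes converge to the analytic solids", {
  geom <- build_geometry(bifurcation_params(), list())
  vol_cyl <- pi * 6^2 * 10  # 1131 cm^3
  v25 <- voxelize(geom, 2.5)
  expect_lt(abs(sum(v25$volumes_cm3[c("TISSUE", "LUMEN")]) - vol_cyl) / vol_cyl,
            0.02)
  v1 <- voxelize(geom, 1)
  err25 <- abs(sum(v25$volumes_cm3[c("TISSUE", "LUMEN")]) - vol_cyl)
  err1 <- abs(sum(v1$volumes_cm3[c("TISSUE", "LUMEN")]) - vol_cyl)
  expect_lt(err1, err25)   # refinement improves the cylinder volume
  expect_lt(err1 / vol_cyl, 0.005)
  # the thin daughter tubes converge too (analytic ~10.2 cm^3; h = 2.5 is
  # ~20% heavy, h = 1 within a few percent)
  expect_lt(abs(v1$volumes_cm3[["LUMEN"]] - 10.2) / 10.2, 0.05)
  # root tube volume under refinement: the top 15 mm hold only root lumen
  # (the daughter tubes flare into the last ~4 mm above the bifurcation point)
  lum1 <- v1$volumes_cm3[["LUMEN"]]
  expect_gt(lum1, 0)
  root_cells <- sum(v1$labels[, , v1$dims[3] - (0:14)] == 2L)
  expect_equal(root_cells * 0.001, pi * 0.5^2 * 1.5, tolerance = 0.04)
})

test_that("voxelize validates resolution", {
  geom <- build_geometry(bifurcation_params(), list())
  expect_error(voxelize(geom, 150), "Lt|resolution")
  expect_error(voxelize(build_geometry(bifurcation_params(),
                                       probe_spec(Dp = 2, Ld = 30)), 2.5),
               "resolution error")
})

test_that("voxelization commutes with mirror reflection", {
  geomp <- suppressWarnings(build_geometry(
    bifurcation_params(),
    probe_spec(Ld = 30, tip_center = c(15, 0, -55))))
  geomm <- suppressWarnings(build_geometry(
    bifurcation_params(),
    probe_spec(Ld = 30, tip_center = c(-15, 0, -55))))
  gp <- voxelize(geomp, 2.5)
  gm <- voxelize(geomm, 2.5)
  expect_identical(gp$labels[gp$dims[1]:1, , ], gm$labels)
})

test_that("interface faces enumerate the lumen-tissue surface once each", {
  fx <- make_fixture("straight_tube", h = 1)
  faces <- interface_faces(fx$grid)
  expect_true(!anyDuplicated(faces[, c("lumen", "tissue")]))
  expect_true(all(fx$grid$labels[faces$lumen] == 2L))
  expect_true(all(fx$grid$labels[faces$tissue] == 1L))
  # lateral area with the L1 staircase bias removed: (pi/4) * n * h^2 vs 2*pi*r*L
  lateral <- sum(faces$area) * pi / 4
  expect_equal(lateral, 2 * pi * 5 * 30, tolerance = 0.15)
  # single lumen cell in tissue: 6 faces
  lab <- array(cryovessel:::LBL[["TISSUE"]], c(3, 3, 3))
  lab[2, 2, 2] <- cryovessel:::LBL[["LUMEN"]]
  g1 <- cryovessel:::make_grid_raw(lab, 1)
  expect_equal(nrow(interface_faces(g1)), 6)
  # no lumen -> error per the contract (needs both regions)
  lab[2, 2, 2] <- cryovessel:::LBL[["TISSUE"]]
  expect_error(interface_faces(cryovessel:::make_grid_raw(lab, 1)),
               "LUMEN")
})

test_that("bifurcation parameter invariants are enforced", {
  expect_error(bifurcation_params(Lt = 90), "L1 \\+ L2")
  expect_error(bifurcation_params(D0 = 130), "smaller")
  expect_error(bifurcation_params(phi = 190), "phi")
  expect_error(probe_spec(Dp = -1), "positive")
  expect_error(probe_spec(axis = c(0, 0, 0)), "nonzero")
})
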