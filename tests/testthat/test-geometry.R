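test_that("margin expansion handles the identity and unit-ball cases", {
  vox <- array(FALSE, c(5, 5, 5)); vox[3, 3, 3] <- TRUE
  m <- structure_mask("GTV", vox, c(1, 1, 1))

  expect_identical(expand_margin(m, 0)$voxels, m$voxels)

  # 1 mm margin at isotropic 1 mm spacing: face-connected 7-voxel cross
  grown <- expand_margin(m, 1)
  expect_equal(sum(grown$voxels), 7)
  expect_true(grown$voxels[3, 3, 3] && grown$voxels[2, 3, 3] &&
                grown$voxels[4, 3, 3] && grown$voxels[3, 2, 3] &&
                grown$voxels[3, 4, 3] && grown$voxels[3, 3, 2] &&
                grown$voxels[3, 3, 4])
})

test_that("expanding a digital sphere matches the distance oracle and the analytic volume", {
  dims <- c(25, 25, 25); sp <- c(1, 1, 1)
  xyz <- expand.grid(i = 1:25, j = 1:25, k = 1:25)
  d <- sqrt((xyz$i - 13)^2 + (xyz$j - 13)^2 + (xyz$k - 13)^2)
  sphere <- structure_mask("S", array(d <= 5, dims), sp)

  grown <- expand_margin(sphere, 5)
  expect_identical(grown$voxels, oracle_dilate(sphere$voxels, sp, 5))

  analytic_cm3 <- 4 / 3 * pi * 10^3 / 1000
  expect_lt(abs(mask_volume_cm3(grown) - analytic_cm3) / analytic_cm3, 0.1)
})

test_that("margin expansion equals the brute-force oracle on random and anisotropic grids", {
  cases <- list(
    list(dims = c(16, 16, 16), sp = c(1, 1, 1),    margin = 2.5, seeds = 6),
    list(dims = c(32, 32, 32), sp = c(2, 2, 2),    margin = 5,   seeds = 10),
    list(dims = c(24, 20, 16), sp = c(1, 2, 3.5),  margin = 4,   seeds = 8),
    list(dims = c(64, 64, 64), sp = c(2, 2, 2),    margin = 6,   seeds = 12))
  for (cs in cases) {
    m <- random_mask(cs$dims, cs$seeds, cs$sp, seed = sum(cs$dims))
    got <- suppressWarnings(expand_margin(m, cs$margin))
    expect_identical(got$voxels, oracle_dilate(m$voxels, cs$sp, cs$margin),
                     info = paste(cs$dims, collapse = "x"))
  }
})

test_that("margin expansion is monotone in the margin and a superset of its input", {
  m <- random_mask(c(20, 20, 20), 5, c(1.5, 1.5, 2), seed = 7)
  prev <- m$voxels
  for (mg in c(0, 1, 2.5, 4, 6)) {
    cur <- suppressWarnings(expand_margin(m, mg))$voxels
    expect_true(all(prev <= cur))  # subset ordering
    prev <- cur
  }
})

test_that("margin expansion rejects negative margins, warns on empty masks and boundary clipping", {
  m <- random_mask(c(8, 8, 8), 2, seed = 3)
  expect_error(expand_margin(m, -1), "non-negative")

  empty <- structure_mask("E", array(FALSE, c(4, 4, 4)), c(1, 1, 1))
  expect_warning(out <- expand_margin(empty, 3), "empty")
  expect_identical(out$voxels, empty$voxels)

  vox <- array(FALSE, c(5, 5, 5)); vox[1, 3, 3] <- TRUE
  edge <- structure_mask("EDGE", vox, c(1, 1, 1))
  expect_warning(expand_margin(edge, 2), "clipped")
})

test_that("normal-lung masks follow the overlap-subtraction rule", {
  dims <- c(12, 12, 12); sp <- c(5, 5, 5)
  lungs_vox <- array(FALSE, dims); lungs_vox[2:11, 2:11, 2:11] <- TRUE
  lungs <- structure_mask("LUNGS", lungs_vox, sp)

  # TOTAL_LUNG leaves the lungs untouched
  expect_identical(normal_lung_mask(lungs, mode = "TOTAL_LUNG")$voxels,
                   lungs$voxels)

  # a fully intrapulmonary target subtracts exactly its own volume
  tgt_vox <- array(FALSE, dims); tgt_vox[4:6, 4:6, 4:6] <- TRUE
  tgt <- structure_mask("PTV", tgt_vox, sp)
  res <- normal_lung_mask(lungs, tgt, "LUNG_MINUS_PTV")
  expect_equal(mask_volume_cm3(res),
               mask_volume_cm3(lungs) - mask_volume_cm3(tgt))
  expect_true(all(res$voxels <= lungs$voxels))

  # an extrapulmonary target is never subtracted
  out_vox <- array(FALSE, dims); out_vox[1, 1, 1] <- TRUE
  outside <- structure_mask("PTV", out_vox, sp)
  expect_identical(normal_lung_mask(lungs, outside, "LUNG_MINUS_PTV")$voxels,
                   lungs$voxels)

  # grid mismatch is rejected
  other <- structure_mask("PTV", array(FALSE, c(6, 6, 6)), sp)
  expect_error(normal_lung_mask(lungs, other, "LUNG_MINUS_PTV"), "same grid")
})

test_that("lung definitions nest when PGTV is inside PTV", {
  ph <- generate_phantom(phantom_config(), seed = 2)
  expect_true(all(ph$masks$PGTV$voxels <= ph$masks$PTV$voxels))
  defs <- lung_definitions(ph$masks$LUNGS, ph$masks$PTV, ph$masks$PGTV)
  expect_true(all(defs$LUNG_MINUS_PTV$voxels <= defs$LUNG_MINUS_PGTV$voxels))
  expect_true(all(defs$LUNG_MINUS_PGTV$voxels <= defs$TOTAL_LUNG$voxels))
})

test_that("phantom serialization round-trips through the binary directory format", {
  ph <- generate_phantom(phantom_config(shape = c(16L, 20L, 16L),
                                        spacing = c(10, 10, 10),
                                        lung_centers = list(c(45, 100, 80),
                                                            c(115, 100, 80)),
                                        lung_semiaxes = c(34, 80, 60),
                                        gtv_center = c(115, 100, 80),
                                        gtv_radius = 16), seed = 5)
  dir <- withr::local_tempdir()
  save_phantom_dir(ph$dose, ph$masks, dir)
  back <- load_phantom_dir(dir)
  expect_equal(back$dose$values, ph$dose$values)
  expect_identical(back$masks$PTV$voxels, ph$masks$PTV$voxels)
  expect_equal(back$dose$spacing, ph$dose$spacing)
})
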