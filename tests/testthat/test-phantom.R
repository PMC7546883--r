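test_that("sphere rasterization follows the voxel-center-in-shape rule", {
  g <- unit_grid(21)
  s <- rasterize_sphere(g, c(10, 10, 10), 0.4, "tiny")
  expect_equal(mask_count(s), 1)

  s10 <- rasterize_sphere(g, c(10, 10, 10), 10, "ball")
  expect_lt(abs(mask_volume(s10) - 4 / 3 * pi * 1000) / (4 / 3 * pi * 1000),
            0.05)

  # a sub-half-voxel sphere at a voxel corner catches no center
  expect_error(rasterize_sphere(g, c(10.5, 10.5, 10.5), 0.1, "x"),
               "empty-structure")
  expect_error(rasterize_sphere(g, c(500, 10, 10), 5, "x"), "invalid-argument")
  expect_error(rasterize_sphere(g, c(10, 10, 10), -1, "x"), "invalid-argument")
})

test_that("tube rasterization spans its axis segment and degenerates to a sphere", {
  g <- unit_grid(21)
  tube <- rasterize_tube(g, c(0, 0, 1), c(10, 10, 10), 0.4, 10, "col")
  expect_equal(mask_count(tube), 11)   # centers z = 5..15 in one column
  idx <- which(tube$voxels, arr.ind = TRUE)
  expect_true(all(idx[, 1] == 11) && all(idx[, 2] == 11))

  deg <- rasterize_tube(g, c(0, 0, 1), c(10, 10, 10), 3, 0, "pt")
  sph <- rasterize_sphere(g, c(10, 10, 10), 3, "pt")
  expect_identical(deg$voxels, sph$voxels)

  g2 <- unit_grid(40)
  diag_tube <- rasterize_tube(g2, c(1, 1, 1), c(19.5, 19.5, 19.5), 6, 14, "d")
  expect_lt(abs(mask_volume(diag_tube) - (pi * 36 * 14 + 4 / 3 * pi * 216)) /
              (pi * 36 * 14 + 4 / 3 * pi * 216), 0.10)
})

test_that("ellipsoid rasterization approaches the analytic volume", {
  g <- unit_grid(41)
  e <- rasterize_ellipsoid(g, c(20, 20, 20), c(12, 8, 6), "E")
  expect_lt(abs(mask_volume(e) - 4 / 3 * pi * 12 * 8 * 6) /
              (4 / 3 * pi * 12 * 8 * 6), 0.05)
})

test_that("translation shifts by whole voxels, preserving count off-boundary", {
  g <- unit_grid(30)
  s <- rasterize_sphere(g, c(12, 12, 12), 5, "s")
  t3 <- perturb(s, perturbation_spec("translate", 3, axis = c(1, 0, 0)))
  expect_equal(mask_count(t3), mask_count(s))
  expect_equal(mask_centroid(t3) - mask_centroid(s), c(3, 0, 0))
  expect_equal(t3$meta$voxel_offset, c(3L, 0L, 0L))
})

test_that("all magnitude-0 perturbations are the identity", {
  s <- random_blob_mask(42)
  for (kind in c("translate", "dilate", "erode", "truncate_axial",
                 "surface_noise")) {
    p <- perturbation_spec(kind, 0)
    expect_identical(perturb(s, p)$voxels, s$voxels, label = kind)
  }
})

test_that("dilation is monotone and erosion antitone", {
  s <- random_blob_mask(7)
  d <- perturb(s, perturbation_spec("dilate", 2))
  e <- perturb(s, perturbation_spec("erode", 1))
  expect_true(all(d$voxels[s$voxels]))          # output superset
  expect_true(all(s$voxels[e$voxels]))          # output subset
  expect_gt(mask_count(d), mask_count(s))
  expect_lt(mask_count(e), mask_count(s))
  # deeper erosion can empty the mask
  expect_error(perturb(s, perturbation_spec("erode", 50)), "empty-structure")
})

test_that("axial truncation removes the stated superior extent", {
  g <- unit_grid(21)
  tube <- rasterize_tube(g, c(0, 0, 1), c(10, 10, 10), 0.4, 10, "col")
  tr <- perturb(tube, perturbation_spec("truncate_axial", 3))
  expect_equal(mask_count(tr), 8)   # centers z = 5..12 remain
  zc <- axis_coords(g)[[3]]
  expect_equal(max(zc[apply(tr$voxels, 3, any)]), 12)
  expect_error(perturb(tube, perturbation_spec("truncate_axial", 30)),
               "empty-structure")
})

test_that("surface noise toggles roughly the expected boundary fraction, reproducibly", {
  g <- unit_grid(30)
  s <- rasterize_sphere(g, c(15, 15, 15), 8, "s")
  p <- perturbation_spec("surface_noise", 0.3, seed = 5L)
  n1 <- perturb(s, p)
  n2 <- perturb(s, p)
  expect_identical(n1$voxels, n2$voxels)        # deterministic given seed
  toggled <- sum(xor(n1$voxels, s$voxels))
  n_bnd <- sum(contourdose:::boundary_voxels(s))
  n_out <- sum(contourdose:::outer_shell_voxels(s))
  expect_gt(toggled, 0.15 * (n_bnd + n_out))
  expect_lt(toggled, 0.45 * (n_bnd + n_out))
  expect_error(perturbation_spec("surface_noise", 1.5), "invalid-argument")
})

test_that("subject simulation is reproducible and honors zero perturbation", {
  spec0 <- prostate_cohort_spec(2, seed = 9, perturbations = list())
  pair <- simulate_subject(spec0, 1)
  for (nm in names(pair$MS$structures))
    expect_identical(pair$AS$structures[[nm]]$voxels,
                     pair$MS$structures[[nm]]$voxels, label = nm)

  spec <- prostate_cohort_spec(2, seed = 9)
  a <- simulate_subject(spec, 2)
  b <- simulate_subject(spec, 2)
  for (nm in names(a$MS$structures)) {
    expect_identical(a$MS$structures[[nm]]$voxels, b$MS$structures[[nm]]$voxels)
    expect_identical(a$AS$structures[[nm]]$voxels, b$AS$structures[[nm]]$voxels)
  }
  expect_error(simulate_subject(spec, 3), "invalid-argument")
})

test_that("perturbation keys must name templates", {
  g <- make_grid(c(24, 24, 24), c(2, 2, 2))
  tpl <- list(structure_template("A", "target", "sphere", radius = 6))
  expect_error(
    cohort_spec(2, g, tpl, list(B = perturbation_spec("dilate", 1))),
    "invalid-argument")
})

test_that("cohorts have the requested size and differ across master seeds", {
  spec1 <- prostate_cohort_spec(5, seed = 1)
  cohort <- simulate_cohort(spec1)
  expect_length(cohort, 5)

  spec2 <- prostate_cohort_spec(5, seed = 2)
  p1 <- simulate_subject(spec1, 1)
  p2 <- simulate_subject(spec2, 1)
  differs <- any(vapply(names(p1$MS$structures), function(nm)
    !identical(p1$MS$structures[[nm]]$voxels, p2$MS$structures[[nm]]$voxels),
    logical(1)))
  expect_true(differs)

  expect_error(prostate_cohort_spec(0), "invalid-argument")
})
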