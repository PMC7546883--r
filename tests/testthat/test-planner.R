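test_that("the dose surrogate hits its plateau, halving and SIB contracts", {
  g <- unit_grid(31)
  tgt <- rasterize_sphere(g, c(15, 15, 15), 0.4, "T", "target")  # one voxel
  set <- structure_set("S", "MS", list(tgt))
  dg <- synthesize_dose(set, dose_params(c(T = 40), falloff_half_distance = 5))

  expect_equal(dg$dose[16, 16, 16], 40)          # in-target plateau
  expect_equal(dg$dose[21, 16, 16], 20)          # exactly h = 5 mm away
  expect_equal(dg$dose[16, 26, 16], 10)          # 2h away -> quartered

  # SIB: the highest prescription rules inside its own target
  g2 <- make_grid(c(48, 48, 48), c(2, 2, 2))
  t70 <- rasterize_sphere(g2, c(47, 47, 47), 8, "PTV70", "target")
  t54 <- rasterize_sphere(g2, c(47, 47, 47), 20, "PTV54", "target")
  sib <- structure_set("S", "MS", list(t70, t54))
  dsib <- synthesize_dose(sib, dose_params(c(PTV70 = 70, PTV54 = 54), 10))
  expect_true(all(dsib$dose[t70$voxels] == 70))
  expect_true(all(dsib$dose[t54$voxels] >= 54))
  expect_equal(max(dsib$dose), 70)
})

test_that("dose decays monotonically with distance from a single target", {
  g <- make_grid(c(48, 48, 48), c(2, 2, 2))
  tgt <- rasterize_sphere(g, c(47, 47, 47), 10, "T", "target")
  set <- structure_set("S", "MS", list(tgt))
  dg <- synthesize_dose(set, dose_params(c(T = 40), 5))
  d <- contourdose:::distance_to(g, tgt$voxels)
  ord <- order(as.vector(d))
  expect_true(all(diff(as.vector(dg$dose)[ord]) <= 1e-12))
})

test_that("shell-averaged dose follows the exponential falloff", {
  g <- make_grid(c(64, 64, 64), c(2, 2, 2))
  tgt <- rasterize_sphere(g, c(63, 63, 63), 12, "T", "target")
  set <- structure_set("S", "MS", list(tgt))
  h <- 8  # > 3x spacing
  dg <- synthesize_dose(set, dose_params(c(T = 40), h))
  dist <- contourdose:::distance_to(g, tgt$voxels)
  for (d0 in c(4, 8, 16)) {
    shell <- dist >= d0 - 1 & dist < d0 + 1
    observed <- mean(dg$dose[shell])
    predicted <- mean(40 * 2^(-dist[shell] / h))
    expect_lt(abs(observed - predicted) / predicted, 0.10)
  }
})

test_that("OAR sparing is a hard in-mask multiplier, monotone in weight", {
  g <- make_grid(c(48, 48, 48), c(2, 2, 2))
  tgt <- rasterize_sphere(g, c(47, 47, 47), 10, "T", "target")
  oar <- rasterize_sphere(g, c(47, 91, 47), 12, "O", "oar")
  set <- structure_set("S", "MS", list(tgt, oar))
  base <- synthesize_dose(set, dose_params(c(T = 40), 5))
  prev <- base$dose
  for (w in c(0.2, 0.5, 0.8)) {
    dw <- synthesize_dose(set, dose_params(c(T = 40), 5,
                                           oar_sparing = c(O = w)))$dose
    expect_true(all(dw <= prev + 1e-12))
    sel <- oar$voxels & !tgt$voxels
    expect_equal(dw[sel], base$dose[sel] * (1 - w))
    expect_equal(dw[!oar$voxels], base$dose[!oar$voxels])
    prev <- dw
  }
})

test_that("background floor and parameter validation behave", {
  g <- unit_grid(15)
  tgt <- rasterize_sphere(g, c(7, 7, 7), 2, "T", "target")
  set <- structure_set("S", "MS", list(tgt))
  dg <- synthesize_dose(set, dose_params(c(T = 40), 2, background_floor = 1))
  expect_gte(min(dg$dose), 1)
  expect_equal(max(dg$dose), 40)

  expect_error(dose_params(c(T = -1), 5), "invalid-argument")
  expect_error(dose_params(c(T = 40), 0), "invalid-argument")
  expect_error(dose_params(c(T = 40), 5, oar_sparing = c(O = 1)),
               "invalid-argument")
  expect_error(synthesize_dose(set, dose_params(c(Missing = 40), 5)),
               "invalid-argument")
})

test_that("plan_for honors its contour source and target policy", {
  spec0 <- prostate_cohort_spec(1, seed = 2, perturbations = list())
  pair0 <- simulate_subject(spec0, 1)
  params <- dose_params(c(CTV = 40), 5, oar_sparing = c(Rectum = 0.3))
  pa <- plan_for(pair0, "AS", params)
  pm <- plan_for(pair0, "MS", params)
  expect_identical(pa$dose, pm$dose)   # AS identical to MS -> same plan

  # perturbed OARs only, targets pinned to MS: plateau region identical
  spec <- prostate_cohort_spec(
    1, seed = 2,
    perturbations = list(Rectum = perturbation_spec("dilate", 4)))
  pair <- simulate_subject(spec, 1)
  pa2 <- plan_for(pair, "AS", params, "always_MS_target")
  pm2 <- plan_for(pair, "MS", params, "always_MS_target")
  ctv <- pair$MS$structures$CTV$voxels
  expect_identical(pa2$dose[ctv], pm2$dose[ctv])
  expect_false(identical(pa2$dose, pm2$dose))
  expect_equal(pa2$meta$target_policy, "always_MS_target")

  bad <- dose_params(c(CTV = 40), 5, oar_sparing = c(Nope = 0.2))
  expect_error(plan_for(pair, "AS", bad), "invalid-argument")
})
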