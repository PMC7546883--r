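test_that("cumulative DVH reproduces simple step functions", {
  g <- unit_grid(8)
  m <- cube_mask(g, 2:5, 2:5, 2:5)
  uniform <- contourdose:::new_dose_grid(g, array(10, g$shape))
  curve <- cumulative_dvh(uniform, m, bin_width = 1)
  expect_equal(curve$edges, 0:11)
  expect_equal(curve$volume_pct, c(rep(100, 11), 0))

  # half the voxels at 40 Gy, half at 0
  dose <- array(0, g$shape)
  dose[2:5, 2:5, 2:3] <- 40
  half <- contourdose:::new_dose_grid(g, dose)
  curve2 <- cumulative_dvh(half, m, bin_width = 1)
  expect_equal(curve2$volume_pct[curve2$edges == 20], 50)
  expect_equal(curve2$volume_pct[1], 100)
  expect_equal(curve2$volume_pct[length(curve2$edges)], 0)
})

test_that("DVH invariants and mean conservation hold on random fields", {
  for (seed in 1:20) {
    m <- random_blob_mask(seed)
    dg <- random_dose_grid(m$grid, seed + 500)
    curve <- cumulative_dvh(dg, m, bin_width = 0.1)
    expect_equal(curve$volume_pct[1], 100)
    expect_true(all(diff(curve$volume_pct) <= 0))
    expect_equal(curve$volume_pct[length(curve$volume_pct)], 0)
    expect_true(all(curve$volume_pct >= 0 & curve$volume_pct <= 100))
    expect_lt(abs(dvh_mean(curve) - dose_mean(dg, m)), 0.1)
  }
})

test_that("bin-free volume-at-dose agrees with the DVH at exact edges", {
  m <- random_blob_mask(31)
  dg <- random_dose_grid(m$grid, 77)
  curve <- cumulative_dvh(dg, m, bin_width = 0.5)
  picks <- seq(1, length(curve$edges), by = 7)
  for (i in picks)
    expect_identical(volume_at_dose(dg, m, curve$edges[i]),
                     curve$volume_pct[i])
})

test_that("endpoint operations match hand counts", {
  g <- unit_grid(4)
  m <- cube_mask(g, 1:2, 1:2, 1:2)   # 8 voxels
  dose <- array(0, g$shape)
  dose[1:2, 1:2, 1] <- c(30, 30, 5, 30)   # 3 voxels >= 20
  dg <- contourdose:::new_dose_grid(g, dose)
  expect_equal(volume_at_dose(dg, m, 20), 37.5)
  expect_equal(volume_at_dose(dg, m, 0), 100)
  expect_equal(volume_at_dose(dg, m, 31), 0)
  expect_equal(dose_max(dg, m), 30)
  expect_equal(dose_mean(dg, m), sum(dose[m$voxels]) / 8)

  empty <- mask_from_array(array(FALSE, c(4, 4, 4)))
  expect_error(dose_mean(dg, empty), "empty-structure")
  other <- cube_mask(unit_grid(5), 1:2, 1:2, 1:2)
  expect_error(dose_max(dg, other), "incompatible-grids")
})

test_that("the constraint grammar parses, round-trips and rejects junk", {
  con <- parse_constraint("V40Gy ≥ 95%")
  expect_equal(con$metric, "V_at_dose")
  expect_equal(con$dose_gy, 40)
  expect_equal(con$limit, 95)
  expect_equal(con$relation, ">=")

  con2 <- parse_constraint("Max <52Gy")
  expect_equal(con2$metric, "max")
  expect_equal(con2$limit, 52)
  expect_equal(con2$relation, "<")

  con3 <- parse_constraint("V45Gy <33%")
  expect_equal(con3[c("metric", "dose_gy", "limit", "relation")],
               list(metric = "V_at_dose", dose_gy = 45, limit = 33,
                    relation = "<"))

  # tolerant of spacing and ASCII relations
  expect_equal(parse_constraint("Mean <40 Gy")$limit, 40)
  expect_equal(parse_constraint("V20Gy<=40%")$relation, "<=")

  # round-trip: canonical rendering re-parses to the same constraint
  tab <- all_constraint_strings()
  for (i in seq_len(nrow(tab))) {
    c1 <- parse_constraint(tab$constraint_text[i], tab$structure[i])
    c2 <- parse_constraint(format(c1), tab$structure[i])
    expect_equal(c1[c("metric", "dose_gy", "limit", "relation")],
                 c2[c("metric", "dose_gy", "limit", "relation")],
                 label = tab$constraint_text[i])
    expect_identical(c1$source_text, tab$constraint_text[i])
  }

  expect_error(parse_constraint("D95 > 40Gy"), "parse error")
  expect_error(parse_constraint("V40Gy > banana"), "parse error")
  expect_error(parse_constraint(""), "parse error")
})

test_that("all shipped constraints evaluate identically to direct voxel math", {
  cons <- c(constraint_table("prostate"), constraint_table("hn"))
  expect_length(cons, 25)
  for (seed in 1:5) {
    m <- random_blob_mask(seed)
    dg <- random_dose_grid(m$grid, seed + 900, max_gy = 80)
    for (con in cons) {
      r <- evaluate_constraint(con, dg, m)
      expected <- direct_endpoint(con, dg, m)
      if (con$metric == "mean")  # summation order differs from the oracle's
        expect_equal(r$achieved, expected, tolerance = 1e-12,
                     label = con$source_text)
      else
        expect_identical(r$achieved, expected, label = con$source_text)
      want_pass <- switch(con$relation,
                          "<" = expected < con$limit,
                          "<=" = expected <= con$limit,
                          ">=" = expected >= con$limit)
      expect_identical(r$passed, want_pass, label = con$source_text)
    }
  }
})

test_that("strict and non-strict relations differ exactly at the limit", {
  g <- unit_grid(4)
  m <- cube_mask(g, 1:2, 1:2, 1:2)
  dg <- contourdose:::new_dose_grid(g, array(45, g$shape))
  strict <- parse_constraint("Max <45Gy")
  loose <- parse_constraint("Max ≤45Gy")
  expect_false(evaluate_constraint(strict, dg, m)$passed)
  expect_true(evaluate_constraint(loose, dg, m)$passed)

  ten <- contourdose:::new_dose_grid(g, array(10, g$shape))
  fifty <- contourdose:::new_dose_grid(g, array(50, g$shape))
  expect_true(evaluate_constraint(strict, ten, m)$passed)
  expect_false(evaluate_constraint(strict, fifty, m)$passed)
})
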