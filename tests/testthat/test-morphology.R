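test_that("region morphology matches analytic shapes", {
  sq <- matrix(FALSE, 14, 14); sq[3:12, 3:12] <- TRUE
  f <- region_morphology(sq)
  expect_equal(unname(f["area"]), 100)
  expect_equal(unname(f["extent"]), 1)
  expect_equal(unname(f["solidity"]), 1)
  expect_equal(unname(f["perimeter"]), 36)

  disk <- raster_ellipse(51, 20, 20)
  fd <- region_morphology(disk)
  expect_equal(unname(fd["equivDiam"]), 40, tolerance = 0.02 * 40)
  expect_lt(unname(fd["eccent"]), 0.1)

  ell <- raster_ellipse(101, 40, 20)    # 2:1 axis ratio
  fe <- region_morphology(ell)
  expect_equal(unname(fe["eccent"]), sqrt(1 - 1 / 4), tolerance = 0.02)
  expect_equal(unname(fe["orientation"]), 0, tolerance = 1)

  expect_error(region_morphology(matrix(FALSE, 5, 5)), "empty")
  multi <- matrix(FALSE, 20, 20)
  multi[2:11, 2:11] <- TRUE; multi[15, 15] <- TRUE
  expect_warning(fm <- region_morphology(multi), "largest")
  expect_equal(unname(fm["area"]), 100)
})

test_that("roundness and compactness follow the printed definitions", {
  disk <- raster_ellipse(41, 15, 15)
  f <- region_morphology(disk)
  expect_equal(unname(f["roundness"]),
               unname(f["equivDiam"] / 2 * f["perimeter"] / f["area"]))
  expect_equal(unname(f["compactness"]),
               unname(f["perimeter"] / f["area"]))
})

test_that("geometric features are translation invariant and scale sanely", {
  base <- matrix(FALSE, 60, 60)
  base[10:25, 12:30] <- TRUE
  shifted <- matrix(FALSE, 60, 60)
  shifted[30:45, 25:43] <- TRUE
  f1 <- region_morphology(base)
  f2 <- region_morphology(shifted)
  expect_equal(f1, f2)
  # integer 2x upscaling: area ~ s^2, perimeter ~ s (within 5%)
  up <- base[rep(1:60, each = 2), rep(1:60, each = 2)]
  fu <- region_morphology(up)
  expect_equal(unname(fu["area"]), unname(4 * f1["area"]))
  expect_equal(unname(fu["perimeter"]), unname(2 * f1["perimeter"]),
               tolerance = 0.05)
})

test_that("gland masks are recovered from masked crops", {
  # filled disk on black: Otsu separates 0 vs > 0 exactly
  disk <- raster_ellipse(71, 30, 30)
  rgbm <- array(0, c(71, 71, 3))
  for (ch in 1:3) rgbm[, , ch] <- disk * 180
  cand <- gland_candidate(rgb_bbox = rgbm, masked_rgb = rgbm,
                          bbox = c(1, 1, 71, 71), patient_id = "P",
                          label = "benign")
  msk <- extract_masks(cand, matrix(FALSE, 71, 71))
  expect_identical(msk$gland_mask, disk)
  expect_false(any(msk$lumen_mask))
  # a hole in the disk is flood-filled
  holed <- disk; holed[34:37, 34:37] <- FALSE
  rgbh <- array(0, c(71, 71, 3))
  for (ch in 1:3) rgbh[, , ch] <- holed * 180
  cand2 <- gland_candidate(rgbh, rgbh, c(1, 1, 71, 71), "P", "benign")
  msk2 <- extract_masks(cand2, matrix(FALSE, 71, 71))
  expect_identical(msk2$gland_mask, disk)
  expect_error(
    extract_masks(gland_candidate(rgbm * 0, rgbm * 0, c(1, 1, 71, 71),
                                  "P", "benign"),
                  matrix(FALSE, 71, 71)),
    "empty gland mask")
})

test_that("phantom candidate masks align with generator truth", {
  spec <- tiny_spec(seed = 17)
  p <- generate_patch(spec, "P04", seed = 6)
  maps <- p$truth_maps
  for (cd in p$candidates[1:2]) {
    cr <- crop_maps(maps, cd$bbox)
    msk <- extract_masks(cd, cr$lumen)
    expect_false(any(msk$lumen_mask & !msk$gland_mask))
    expect_gte(jaccard(msk$gland_mask, cd$truth_gland_mask), 0.8)
    if (any(cd$truth_lumen_mask)) {
      expect_gte(jaccard(msk$lumen_mask, cd$truth_lumen_mask), 0.8)
    }
  }
})

test_that("the 20 morphology features behave across gland and lumen", {
  disk <- raster_ellipse(41, 15, 15)
  masks <- structure(list(gland_mask = disk, lumen_mask = disk),
                     class = "candidate_masks")
  v <- morphological_features(masks)
  expect_length(v, 20)
  expect_equal(unname(v[1:10]), unname(v[11:20]))  # lumen == gland here
  masks0 <- structure(list(gland_mask = disk,
                           lumen_mask = disk & FALSE),
                      class = "candidate_masks")
  v0 <- morphological_features(masks0)
  expect_true(all(v0[11:20] == 0))
  expect_false(attr(v0, "lumen_valid"))
})
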