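# Slice selection, mirror placement about the midline column, the HU/lesion
# validity rules, and symmetry-preserving repositioning.

test_that("analysis-slice selection picks the nearest height, ties low", {
  v <- make_volume(replicate(12, matrix(25, 4, 4), simplify = FALSE),
                   heights = seq(0, 110, 10))
  expect_equal(select_analysis_slice(v, 60)$slice_height_mm, 60)

  v2 <- make_volume(replicate(3, matrix(25, 4, 4), simplify = FALSE),
                    heights = c(0, 55, 65))
  expect_equal(select_analysis_slice(v2, 60)$slice_height_mm, 55)

  v1 <- make_volume(list(matrix(25, 4, 4)), heights = 5)
  expect_equal(select_analysis_slice(v1, 60)$slice_height_mm, 5)
})

test_that("six patches are placed, mirror-symmetric about the midline", {
  set.seed(3)
  sl <- make_slice(matrix(sample(0:50, 200 * 200, TRUE), 200, 200))
  m <- 100L
  offs <- list(AH = c(row = 40, dcol = 10), TL = c(row = 90, dcol = 55),
               PH = c(row = 150, dcol = 12))
  patches <- place_rois(sl, m, offs, "left")
  expect_length(patches, 6)
  counts <- table(sapply(patches, `[[`, "region"))
  expect_equal(as.vector(counts[c("AH", "PH", "TL")]), c(2L, 2L, 2L))
  for (rg in c("AH", "TL", "PH")) {
    pr <- patches[sapply(patches, `[[`, "region") == rg]
    cols1 <- pr[[1]]$origin["col"] + 0:19
    cols2 <- pr[[2]]$origin["col"] + 0:19
    # reflection about m: column x pairs with 2m - x
    expect_equal(sort(unname(2 * m - cols1)), sort(unname(cols2)))
    expect_equal(pr[[1]]$origin["row"], pr[[2]]$origin["row"])
  }
  sides <- sapply(patches, `[[`, "side")
  left_of_mid <- sapply(patches, function(p) p$origin["col"] < m)
  expect_true(all(sides[left_of_mid] == "hemorrhagic"))
  expect_true(all(sides[!left_of_mid] == "contralateral"))
})

test_that("relabeling the hemorrhagic side changes tags, not pixels", {
  set.seed(4)
  sl <- make_slice(matrix(sample(0:50, 200 * 200, TRUE), 200, 200))
  offs <- list(AH = c(row = 40, dcol = 10), TL = c(row = 90, dcol = 55),
               PH = c(row = 150, dcol = 12))
  a <- place_rois(sl, 100L, offs, "left")
  b <- place_rois(sl, 100L, offs, "right")
  expect_identical(lapply(a, `[[`, "pixels"), lapply(b, `[[`, "pixels"))
  expect_false(identical(sapply(a, `[[`, "side"), sapply(b, `[[`, "side")))
})

test_that("out-of-bounds placement errors name the offending region", {
  sl <- make_slice(matrix(25, 60, 60))
  offs <- list(AH = c(row = 50, dcol = 5), TL = c(row = 10, dcol = 5),
               PH = c(row = 20, dcol = 5))
  expect_error(place_rois(sl, 30L, offs, "left"), "AH")
})

test_that("validation applies the inclusive HU window and mask overlap", {
  ok <- make_patch(matrix(25, 20, 20))
  expect_true(validate_roi(ok)$valid)

  one_hot <- matrix(25, 20, 20); one_hot[3, 7] <- 51
  v <- validate_roi(make_patch(one_hot))
  expect_false(v$valid)
  expect_equal(v$violations$rule, "HU window")
  expect_equal(v$violations$count, 1)
  # boundaries 0 and 50 are inside the window
  expect_true(validate_roi(make_patch(matrix(c(0, 50), 20, 20)))$valid)

  mask <- matrix(FALSE, 40, 40); mask[1:2, 3] <- TRUE; mask[5, 5] <- TRUE
  v2 <- validate_roi(make_patch(matrix(25, 20, 20)), hematoma_mask = mask)
  expect_false(v2$valid)
  expect_equal(v2$violations$rule, "hematoma overlap")
  expect_equal(v2$violations$count, 3)

  expect_error(validate_roi(ok, hematoma_mask = matrix(FALSE, 10, 10)),
               "shape")
})

test_that("repositioning finds the nearest valid origin, mirror-compatibly", {
  sl <- make_slice(matrix(25, 60, 60))
  p <- make_patch(sl$pixels[10:29, 10:29], origin = c(10, 10))
  expect_identical(auto_reposition(p, sl)$origin, p$origin)

  # block the patch's first column only: nearest fix is one step right
  mask <- matrix(FALSE, 60, 60)
  mask[, 10] <- TRUE
  moved <- auto_reposition(p, sl, ventricle_mask = mask)
  expect_equal(unname(moved$origin), c(10, 11))
  expect_equal(unname(attr(moved, "displacement")), c(0, 1))
  # exhaustive check: no valid placement at distance < 1
  expect_false(validate_roi(p, ventricle_mask = mask)$valid)

  expect_error(auto_reposition(p, sl, ventricle_mask = mask,
                               search_radius_px = 0), "radius 0")
})

test_that("paired patches on a symmetric phantom are pixel multiset equal", {
  pt <- generate_patient(phantom_params(
    icp_mmhg = 10, seed = 21, slice_heights_mm = c(50, 60),
    hematoma_volume_ml = 0, mirror_noise = TRUE))
  rois <- extract_patient_rois(pt)
  for (i in c(1, 3, 5)) {
    expect_identical(sort(as.vector(rois[[i]]$pixels)),
                     sort(as.vector(rois[[i + 1]]$pixels)))
  }
})

test_that("phantom ROIs validate against the ground-truth masks", {
  for (seed in c(1, 8)) {
    pt <- quick_phantom(icp = 38, seed = seed)
    sl <- select_analysis_slice(pt$volume, 60)
    k <- which(slice_heights(pt$volume) == sl$slice_height_mm)
    rois <- extract_patient_rois(pt)
    expect_length(rois, 6)
    for (p in rois)
      expect_true(validate_roi(p, c(0, 50), pt$truth$hematoma_mask[[k]],
                               pt$truth$ventricle_mask[[k]])$valid)
  }
})
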