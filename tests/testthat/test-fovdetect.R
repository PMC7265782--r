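test_that("downsample dimensions, identity and constant invariance", {
  img <- array(runif(330 * 170 * 3, 0, 255), c(330, 170, 3))
  out <- downsample(img, 16)
  expect_equal(dim(out)[1:2], c(ceiling(330 / 16), ceiling(170 / 16)))
  expect_equal(downsample(img, 1), img, tolerance = 1e-12)
  expect_error(downsample(img, 0), "factor")

  flat <- array(120, c(64, 48, 3))
  expect_true(all(downsample(flat, 8) == 120))

  # 3200x3200 at 16:1 -> 200x200 (the reference geometry); verified on the
  # cheap all-constant raster
  big <- array(200, c(3200, 3200, 3))
  expect_equal(dim(downsample(big, 16))[1:2], c(200, 200))
})

test_that("cluster_tissue separates flat color regions with the corner rule", {
  img <- array(0, c(30, 30, 3))
  for (ch in 1:3) img[, , ch] <- 250            # white background
  img[10:20, 3:12, 1] <- 230; img[10:20, 3:12, 2] <- 160; img[10:20, 3:12, 3] <- 180
  img[10:20, 18:27, 1] <- 120; img[10:20, 18:27, 2] <- 80; img[10:20, 18:27, 3] <- 160
  cl <- cluster_tissue(img, k = 3, seed = 1)
  expect_equal(cl$background_label, cl$labels[1, 1])
  want <- matrix(FALSE, 30, 30)
  want[10:20, 3:12] <- TRUE; want[10:20, 18:27] <- TRUE
  expect_identical(cl$tissue_mask, want)

  # all-white image: degenerate, everything is background
  white <- array(250, c(10, 10, 3))
  cl2 <- suppressWarnings(cluster_tissue(white, k = 3, seed = 1))
  expect_false(any(cl2$tissue_mask))
})

test_that("largest_tissue_bbox finds tight boxes and breaks ties", {
  m <- matrix(FALSE, 30, 30)
  m[6:15, 6:15] <- TRUE
  b <- largest_tissue_bbox(m)
  expect_equal(unclass(b), c(r0 = 5L, c0 = 5L, r1 = 15L, c1 = 15L))

  # two components of 100 px and 400 px: the larger wins
  m[20:29, 1:10] <- TRUE # 100 px (later in scan)
  m2 <- matrix(FALSE, 40, 40)
  m2[2:11, 2:11] <- TRUE          # 100 px
  m2[15:34, 15:34] <- TRUE        # 400 px
  b2 <- largest_tissue_bbox(m2)
  expect_equal(unclass(b2), c(r0 = 14L, c0 = 14L, r1 = 34L, c1 = 34L))

  # exact size tie: the component discovered first in row-major order wins
  m3 <- matrix(FALSE, 20, 20)
  m3[2:4, 2:4] <- TRUE
  m3[10:12, 10:12] <- TRUE
  b3 <- largest_tissue_bbox(m3)
  expect_equal(b3[["r0"]], 1L)

  expect_null(largest_tissue_bbox(matrix(FALSE, 5, 5)))
})

test_that("identify_fov recovers the planted tissue box", {
  gen <- generate_slide(test_slide_spec(seed = 31))
  fov <- identify_fov(gen$slide, seed = 31)
  expect_gte(box_iou(fov$bbox_full, gen$truth$tissue_bbox), 0.9)
  # low-res -> full-res round trip within one factor-sized pixel
  expect_true(all(abs(as.integer(fov$bbox_full) -
                      as.integer(fov$bbox_low) * fov$factor) <= fov$factor))
})

test_that("identify_fov picks the larger of two blobs (1:4 area ratio)", {
  spec <- slide_spec(
    width = 1200, height = 1200, seed = 41,
    tissue_blobs = list(
      list(center = c(300, 300), radius = 130, color = c(226, 158, 180)),
      list(center = c(800, 800), radius = 260, color = c(226, 158, 180))
    )
  )
  gen <- generate_slide(spec)
  fov <- identify_fov(gen$slide, seed = 41)
  big <- til_box(800 - 260, 800 - 260, 800 + 260, 800 + 260)
  expect_gte(box_iou(fov$bbox_full, big), 0.85)
  # the small blob is outside the FOV
  expect_gte(fov$bbox_full[["r0"]], 430)
})

test_that("FOV is equivariant under factor-aligned translation", {
  mk <- function(dr, dc) {
    slide_spec(width = 960, height = 960, seed = 17,
               tissue_blobs = list(list(center = c(400 + dr, 400 + dc),
                                        radius = 200,
                                        color = c(226, 158, 180))))
  }
  f0 <- identify_fov(generate_slide(mk(0, 0))$slide, seed = 17)
  f1 <- identify_fov(generate_slide(mk(96, 64))$slide, seed = 17)
  shift <- as.integer(f1$bbox_full) - as.integer(f0$bbox_full)
  expect_true(all(abs(shift - c(96, 64, 96, 64)) <= 16))
})

test_that("no tissue yields a diagnostic", {
  white <- raster_slide(array(250L, c(256, 256, 3)))
  expect_error(suppressWarnings(identify_fov(white)), "no tissue")
})
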