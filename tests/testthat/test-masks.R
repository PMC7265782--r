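test_that("centers_to_mask matches the per-pixel distance oracle", {
  expect_false(any(centers_to_mask(NULL, c(50, 50))))

  # single centered disc: lattice count for radius 16
  m <- centers_to_mask(cbind(100, 100), c(200, 200), 32)
  grid <- expand.grid(r = 0:199, c = 0:199)
  oracle <- sum((grid$r - 100)^2 + (grid$c - 100)^2 <= 16^2)
  expect_equal(sum(m), oracle)

  # random center sets vs brute force, including border clipping
  for (s in 1:5) {
    set.seed(s)
    n <- sample(1:6, 1)
    ctr <- cbind(runif(n, -5, 105), runif(n, -5, 105))
    dm <- sample(c(9, 16, 32), 1)
    m <- centers_to_mask(ctr, c(100, 100), dm)
    g <- expand.grid(r = 0:99, c = 0:99)
    inside <- rep(FALSE, nrow(g))
    for (i in seq_len(n)) {
      inside <- inside |
        ((g$r - ctr[i, 1])^2 + (g$c - ctr[i, 2])^2 <= (dm / 2)^2)
    }
    expect_equal(as.vector(m), inside)
  }

  # union subadditivity for overlapping discs
  one <- sum(centers_to_mask(cbind(50, 50), c(100, 100), 32))
  two <- sum(centers_to_mask(rbind(c(50, 46), c(50, 54)), c(100, 100), 32))
  expect_lt(two, 2 * one)
  expect_error(centers_to_mask(cbind(1, 1), c(10, 10), 0), "diameter")
})

test_that("augment is reproducible, involutive and slices masks correctly", {
  set.seed(2)
  patch <- array(sample(0:255, 64 * 64 * 3, TRUE), c(64, 64, 3))
  mask <- matrix(runif(64 * 64) < 0.2, 64, 64)

  a1 <- augment(patch, mask, seed = 5, crop_size = 32)
  a2 <- augment(patch, mask, seed = 5, crop_size = 32)
  expect_identical(a1, a2)

  # horizontal mirror applied twice is the identity
  mir <- patch[, 64:1, , drop = FALSE]
  expect_identical(mir[, 64:1, , drop = FALSE], patch)

  # the same transform hits patch and mask: re-derive the mask from the
  # patch's red channel
  patch2 <- patch
  patch2[, , 1] <- mask * 255
  a3 <- augment(patch2, mask, seed = 9, crop_size = 40)
  expect_identical(a3$patch[, , 1] > 0, unname(a3$mask))
  expect_equal(dim(a3$mask), c(40, 40))

  expect_error(augment(patch, mask, seed = 1, crop_size = 100), "crop")
})

test_that("mask construction commutes with mirroring the centers", {
  set.seed(4)
  ctr <- cbind(runif(5, 10, 90), runif(5, 10, 90))
  m <- centers_to_mask(ctr, c(100, 100), 24)
  ctr_m <- cbind(ctr[, 1], 99 - ctr[, 2]) # horizontal mirror, 0-based
  m_m <- centers_to_mask(ctr_m, c(100, 100), 24)
  expect_identical(m[, 100:1], m_m)
})

test_that("extract_detections reduces components to centroids", {
  expect_equal(nrow(extract_detections(matrix(FALSE, 50, 50))), 0L)

  m <- centers_to_mask(cbind(60, 70), c(120, 120), 32)
  det <- extract_detections(m)
  expect_equal(nrow(det), 1L)
  expect_lt(max(abs(det - c(60, 70))), 0.5)

  # small specks below min_area are dropped
  m[1:3, 1:3] <- TRUE
  expect_equal(nrow(extract_detections(m, min_area = 80)), 1L)

  # two heavily overlapping discs merge to one centroid (documented)
  m2 <- centers_to_mask(rbind(c(50, 45), c(50, 60)), c(100, 100), 32)
  expect_equal(max(tilscope:::cpp_label_components(m2, 8L)), 1L)
  expect_equal(nrow(extract_detections(m2)), 1L)
})

test_that("evaluate_detections: exact match, empty predictions, conventions", {
  truth <- cbind(c(10, 40, 80), c(10, 40, 80))
  r <- evaluate_detections(truth, truth)
  expect_equal(c(r$precision, r$recall, r$f1), c(1, 1, 1))

  r0 <- evaluate_detections(matrix(0, 0, 2), truth)
  expect_equal(r0$recall, 0)
  expect_equal(r0$precision, 0)
  expect_true(r0$precision_undefined)

  # one-to-one: two predictions cannot claim one truth
  r1 <- evaluate_detections(rbind(c(10, 10), c(10, 12)), cbind(10, 10))
  expect_equal(r1$tp, 1L)
  expect_equal(r1$fp, 1L)
})

test_that("greedy matching attains the optimal matching on small instances", {
  for (s in 1:30) {
    inst <- random_detection_instance(s)
    r <- evaluate_detections(inst$pred, inst$truth, radius = 16)
    expect_equal(r$tp, bf_max_matching(inst$pred, inst$truth, 16))
  }
})

test_that("detection metrics respect their structural bounds", {
  set.seed(11)
  pred <- matrix(runif(20, 0, 50), ncol = 2)
  truth <- matrix(runif(16, 0, 50), ncol = 2)
  radii <- c(2, 4, 8, 16, 32)
  tps <- vapply(radii, function(rd) evaluate_detections(pred, truth, rd)$tp, 0L)
  expect_true(all(diff(tps) >= 0)) # TP monotone nondecreasing in radius
  r <- evaluate_detections(pred, truth, 16)
  expect_lte(r$f1, min(2 * r$precision, 2 * r$recall) + 1e-12)
})
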