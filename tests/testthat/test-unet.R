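# Unit tests of the segmentation network machinery at miniature scale
# (base width 2, small patches); the full desk-scale runs live in
# test-acceptance.R.

tiny_patch_set <- function(n, size = 64, density = 4e-4, seed = 1) {
  spec <- slide_spec(seed = seed, lymph_density = density,
                     lymph_diameter = 16, min_separation = 18,
                     distractor_density = 0)
  generate_annotated_patches(n, spec, patch_size = size, seed = seed)
}

test_that("analytic gradients agree with finite differences", {
  cfg <- seg_model_config(base_width = 2, seed = 3)
  params <- tilscope:::init_params(cfg)
  set.seed(1)
  x <- array(runif(32 * 32 * 3), c(32, 32, 3))
  y <- matrix(rbinom(32 * 32, 1, 0.3), 32, 32)
  for (loss in c("bce", "dice")) {
    lg <- tilscope:::cpp_unet_loss_grad(params, x, y, cfg$widths, cfg$in_ch,
                                        loss)
    set.seed(2)
    eps <- 1e-6
    for (nm in sample(names(params), 6)) {
      i <- sample(length(params[[nm]]), 1)
      pp <- params; pp[[nm]][i] <- pp[[nm]][i] + eps
      lp <- tilscope:::cpp_unet_loss_grad(pp, x, y, cfg$widths, cfg$in_ch,
                                          loss)$loss
      pm <- params; pm[[nm]][i] <- pm[[nm]][i] - eps
      lm <- tilscope:::cpp_unet_loss_grad(pm, x, y, cfg$widths, cfg$in_ch,
                                          loss)$loss
      num <- (lp - lm) / (2 * eps)
      ana <- lg$grads[[nm]][i]
      expect_lt(abs(num - ana), 1e-4 * max(1, abs(num)))
    }
  }
})

test_that("training reduces validation loss and is seed-deterministic", {
  aps <- tiny_patch_set(12, seed = 21)
  sp <- split_patches(aps, 0.75, seed = 21)
  cfg <- seg_model_config(base_width = 2, epochs = 3, crop_size = 48,
                          seed = 21)
  ck1 <- train_model(cfg, sp$train, sp$test)
  expect_lte(ck1$log$val_loss[nrow(ck1$log)], ck1$log$val_loss[1])
  ck2 <- train_model(cfg, sp$train, sp$test)
  expect_identical(ck1$params, ck2$params)
  expect_equal(ck1$log, ck2$log)
})

test_that("training on all-empty masks predicts near-empty masks", {
  spec <- slide_spec(seed = 22, lymph_density = 0, distractor_density = 0)
  aps <- generate_annotated_patches(8, spec, patch_size = 64, seed = 22)
  sp <- split_patches(aps, 0.75, seed = 22)
  cfg <- seg_model_config(base_width = 2, epochs = 3, crop_size = 48,
                          seed = 22)
  ck <- train_model(cfg, sp$train, sp$test)
  pm <- predict_mask(ck, sp$test$patches[[1]]$pixels)
  expect_lt(mean(pm$mask), 0.02)
})

test_that("predict_mask is deterministic, bounded, and validates shape", {
  aps <- tiny_patch_set(4, seed = 23)
  cfg <- seg_model_config(base_width = 2, epochs = 1, crop_size = 48,
                          seed = 23)
  sp <- list(train = aps, test = aps)
  ck <- train_model(cfg, sp$train, sp$test)
  p1 <- predict_mask(ck, aps$patches[[1]]$pixels)
  p2 <- predict_mask(ck, aps$patches[[1]]$pixels)
  expect_identical(p1, p2)
  expect_true(all(p1$prob >= 0 & p1$prob <= 1))
  expect_identical(dim(p1$prob), dim(aps$patches[[1]]$pixels)[1:2])
  expect_error(predict_mask(ck, matrix(0, 10, 10)), "rows, cols")
})

test_that("checkpoints round-trip through disk", {
  aps <- tiny_patch_set(4, seed = 24)
  cfg <- seg_model_config(base_width = 2, epochs = 1, crop_size = 48,
                          seed = 24)
  ck <- train_model(cfg, aps, aps)
  path <- file.path(tempdir(), "ck_test")
  save_checkpoint(ck, path)
  ck2 <- load_checkpoint(path)
  x <- aps$patches[[1]]$pixels
  expect_identical(predict_mask(ck, x), predict_mask(ck2, x))
  expect_true(file.exists(paste0(path, ".json")))
})

test_that("cascade_round refines, skips failing patches, and stops on the proxy", {
  aps <- tiny_patch_set(8, seed = 25)
  cfg <- seg_model_config(base_width = 2, epochs = 2, crop_size = 48,
                          seed = 25)
  ck <- train_model(cfg, aps, aps)

  # identity refiner: a self-training round still returns a valid checkpoint
  ck_id <- cascade_round(ck, aps, refiner_identity(), epochs = 1)
  expect_s3_class(ck_id, "seg_checkpoint")
  expect_equal(ck_id$cascade_log$n_used, 8L)

  # a refiner that fails on one patch: that patch is skipped
  flaky <- function(patch, mask, index) {
    if (index == 3) stop("refiner unavailable")
    centers_to_mask(aps$patches[[index]]$centers, dim(mask), 16)
  }
  ck_fl <- cascade_round(ck, aps, flaky, epochs = 1)
  expect_equal(ck_fl$cascade_log$skipped, 3L)
  expect_equal(ck_fl$cascade_log$n_used, 7L)

  # stopping rule: a refiner that returns the predictions themselves gives
  # accuracy proxy 1 >= 0.9, so cascade_train performs zero rounds
  ct <- cascade_train(ck, aps, refiner_identity(), max_rounds = 2)
  expect_equal(ct$rounds_run, 0L)
  expect_identical(ct$params, ck$params)
  expect_equal(ct$stage, "U2")
})
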