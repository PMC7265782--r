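# Training, prediction and cascade refinement for the lymphocyte
# segmentation network. The architecture (five stride-2 residual encoder
# stages, five decoder upsampling blocks of 2x2 transposed conv + skip
# concatenation + two 3x3 convs, 1x1 output head) lives in src/unet.cpp;
# this file owns initialization, the optimizer loop and checkpoints.

#' Segmentation model configuration
#'
#' @param base_width channels of the first encoder stage; stages use
#'   `c(w, 2w, 4w, 8w, 8w)`. Default 8 ("desk scale"); 64 matches a full
#'   ResNet18-width encoder.
#' @param loss `"bce"` (pixelwise binary cross-entropy, default) or
#'   `"dice"`.
#' @param lr Adam learning rate.
#' @param epochs training epochs (default 12; the synthetic task converges
#'   well before the ~200 epochs full-scale stain data needs).
#' @param batch_size gradients are accumulated over this many patches per
#'   update.
#' @param crop_size random-crop side used during training augmentation
#'   (must be a multiple of 32 to avoid decoder cropping); prediction is
#'   fully convolutional and uses whole patches.
#' @param threshold binarization threshold on the sigmoid output.
#' @param min_area minimum component area (px) for detection extraction.
#' @param match_radius center-matching radius (px) for evaluation.
#' @param lymph_diameter nucleus diameter (px) used to build masks.
#' @param seed RNG seed controlling init, shuffling and augmentation.
#' @return object of class `seg_config`.
#' @export
seg_model_config <- function(base_width = 8L, loss = c("bce", "dice"),
                             lr = 2e-3, epochs = 12L, batch_size = 4L,
                             crop_size = 96L, threshold = 0.5,
                             min_area = 80, match_radius = 16,
                             lymph_diameter = 32, seed = 1L) {
  loss <- match.arg(loss)
  stopifnot(base_width >= 1, epochs >= 1, batch_size >= 1)
  widths <- as.integer(base_width * c(1, 2, 4, 8, 8))
  structure(list(base_width = as.integer(base_width), widths = widths,
                 in_ch = 3L, loss = loss, lr = lr,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 crop_size = as.integer(crop_size), threshold = threshold,
                 min_area = min_area, match_radius = match_radius,
                 lymph_diameter = lymph_diameter, seed = as.integer(seed)),
            class = "seg_config")
}

# Xavier-uniform initialization of all weights (biases zero); the encoder is
# randomly initialized too - no pretrained weights are available offline.
init_params <- function(config) {
  shapes <- cpp_unet_shapes(config$widths, config$in_ch)
  with_seed(derive_seed(config$seed, "init"), {
    params <- lapply(names(shapes), function(nm) {
      d <- shapes[[nm]]
      if (length(d) == 2L) {
        a <- sqrt(6 / (d[1] + d[2]))
        matrix(runif(d[1] * d[2], -a, a), d[1], d[2])
      } else {
        numeric(d[1])
      }
    })
    names(params) <- names(shapes)
    params
  })
}

patch_to_cube <- function(px) array(as.double(px) / 255, dim(px))

masks_for_set <- function(aps, diameter) {
  lapply(aps$patches, function(p) {
    centers_to_mask(p$centers, c(dim(p$pixels)[1], dim(p$pixels)[2]), diameter)
  })
}

# evaluation-only mean loss (forward pass, no gradients)
mean_loss <- function(params, config, patches, masks) {
  tot <- 0
  for (i in seq_along(patches)) {
    p <- cpp_unet_predict(params, patch_to_cube(patches[[i]]$pixels),
                          config$widths, config$in_ch)
    y <- masks[[i]] * 1
    tot <- tot + if (config$loss == "bce") {
      p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
      mean(-y * log(p) - (1 - y) * log(1 - p))
    } else {
      1 - (2 * sum(p * y) + 1) / (sum(p) + sum(y) + 1)
    }
  }
  tot / length(patches)
}

#' Train the segmentation model
#'
#' Masks are built from the center annotations via [centers_to_mask()];
#' training patches are augmented by random mirror and random crop. Adam
#' optimization of the configured loss; per-epoch train/validation losses
#' are logged. Aborts with a diagnostic on NaN loss.
#'
#' @param config a [seg_model_config()].
#' @param train,val `annotated_patches` sets (nonempty).
#' @param init optional starting checkpoint (used by cascade rounds).
#' @param epochs overrides `config$epochs` when given.
#' @return object of class `seg_checkpoint`: `list(params, config, log,
#'   stage)` where `log` is a data frame of per-epoch losses.
#' @export
train_model <- function(config, train, val, init = NULL, epochs = NULL) {
  stopifnot(inherits(config, "seg_config"),
            length(train$patches) > 0, length(val$patches) > 0)
  epochs <- as.integer(epochs %||% config$epochs)
  params <- if (is.null(init)) init_params(config) else init$params
  masks_tr <- masks_for_set(train, config$lymph_diameter)
  masks_va <- masks_for_set(val, config$lymph_diameter)

  # Adam state
  mstate <- lapply(params, function(p) p * 0)
  vstate <- lapply(params, function(p) p * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L
  n <- length(train$patches)
  log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                    val_loss = numeric(0))

  for (ep in seq_len(epochs)) {
    ord <- with_seed(derive_seed(config$seed, paste0("shuffle", ep)),
                     sample.int(n))
    ep_loss <- 0
    acc <- NULL; acc_n <- 0L
    for (ii in seq_along(ord)) {
      i <- ord[ii]
      p <- train$patches[[i]]
      aug <- augment(p$pixels, masks_tr[[i]],
                     seed = derive_seed(config$seed,
                                        sprintf("aug%d_%d", ep, i)),
                     crop_size = min(config$crop_size, dim(p$pixels)[1]))
      lg <- cpp_unet_loss_grad(params, patch_to_cube(aug$patch),
                               aug$mask * 1, config$widths, config$in_ch,
                               config$loss)
      if (!is.finite(lg$loss)) {
        stop(sprintf("training diverged (non-finite loss at epoch %d, patch %d)",
                     ep, i))
      }
      ep_loss <- ep_loss + lg$loss
      acc <- if (is.null(acc)) lg$grads else {
        Map(`+`, acc, lg$grads)
      }
      acc_n <- acc_n + 1L
      if (acc_n == config$batch_size || ii == n) {
        step <- step + 1L
        for (nm in names(params)) {
          g <- acc[[nm]] / acc_n
          mstate[[nm]] <- b1 * mstate[[nm]] + (1 - b1) * g
          vstate[[nm]] <- b2 * vstate[[nm]] + (1 - b2) * g^2
          mhat <- mstate[[nm]] / (1 - b1^step)
          vhat <- vstate[[nm]] / (1 - b2^step)
          params[[nm]] <- params[[nm]] - config$lr * mhat / (sqrt(vhat) + eps)
        }
        acc <- NULL; acc_n <- 0L
      }
    }
    vl <- mean_loss(params, config, val$patches, masks_va)
    log <- rbind(log, data.frame(epoch = ep, train_loss = ep_loss / n,
                                 val_loss = vl))
  }
  structure(list(params = params, config = config, log = log, stage = "U1"),
            class = "seg_checkpoint")
}

#' @method print seg_checkpoint
#' @export
print.seg_checkpoint <- function(x, ...) {
  last <- x$log[nrow(x$log), ]
  cat(sprintf("<seg_checkpoint stage %s, width %d, %d epochs, val loss %.4f>\n",
              x$stage, x$config$base_width, nrow(x$log),
              if (nrow(x$log)) last$val_loss else NA))
  invisible(x)
}

#' Predict a lymphocyte probability map and binary mask
#'
#' Fully convolutional: any patch size works (sizes are handled by the
#' decoder's crop-to-skip rule).
#'
#' @param ckpt a `seg_checkpoint`.
#' @param patch `[rows, cols, 3]` RGB array (0..255).
#' @param threshold overrides the config binarization threshold.
#' @return `list(prob = numeric matrix in [0,1], mask = logical matrix)`.
#' @export
predict_mask <- function(ckpt, patch, threshold = NULL) {
  stopifnot(inherits(ckpt, "seg_checkpoint"))
  if (length(dim(patch)) != 3L || dim(patch)[3] != ckpt$config$in_ch) {
    stop("patch must be [rows, cols, 3]")
  }
  thr <- threshold %||% ckpt$config$threshold
  prob <- cpp_unet_predict(ckpt$params, patch_to_cube(patch),
                           ckpt$config$widths, ckpt$config$in_ch)
  list(prob = prob, mask = prob >= thr)
}

#' Evaluate a checkpoint's detection performance on a patch set
#'
#' @param ckpt a `seg_checkpoint`.
#' @param aps an `annotated_patches` set.
#' @return `list(precision, recall, f1, per_patch)` pooled over all patches
#'   (counts summed, then precision/recall/F1).
#' @export
evaluate_checkpoint <- function(ckpt, aps) {
  tp <- fp <- fn <- 0
  per <- lapply(aps$patches, function(p) {
    pm <- predict_mask(ckpt, p$pixels)
    det <- extract_detections(pm$mask, ckpt$config$min_area)
    evaluate_detections(det, p$centers, ckpt$config$match_radius)
  })
  for (r in per) { tp <- tp + r$tp; fp <- fp + r$fp; fn <- fn + r$fn }
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 1 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else {
    2 * precision * recall / (precision + recall)
  }
  list(precision = precision, recall = recall, f1 = f1, tp = tp, fp = fp,
       fn = fn, per_patch = per)
}

dice_coef <- function(a, b) {
  s <- sum(a) + sum(b)
  if (s == 0) return(1)
  2 * sum(a & b) / s
}

#' Mask refiner that accepts predictions unchanged (self-training)
#' @return a refiner function `(patch, mask, index) -> mask`.
#' @export
refiner_identity <- function() function(patch, mask, index) mask

#' Mask refiner that substitutes ground-truth masks
#'
#' Stands in for the expert reviewers of the original cascade scheme: given
#' the annotated group, returns each patch's true disc mask regardless of
#' the prediction.
#'
#' @param group the `annotated_patches` group being refined.
#' @param diameter nucleus diameter for mask construction.
#' @return a refiner function `(patch, mask, index) -> mask`.
#' @export
refiner_ground_truth <- function(group, diameter = 32) {
  masks <- masks_for_set(group, diameter)
  function(patch, mask, index) masks[[index]]
}

#' One cascade refinement round
#'
#' Predicts on the (new, unannotated) patch group, passes every prediction
#' through the refiner, and retrains from the current weights on the
#' refined masks. A refiner failure on a patch skips that patch with a log
#' entry. The mean per-patch Dice between predictions and refined masks is
#' the programmatic stand-in for the expert "prediction accuracy"; rounds
#' stop when it reaches `stop_dice`.
#'
#' @param ckpt starting `seg_checkpoint`.
#' @param group `annotated_patches` group (annotations only used by a
#'   ground-truth refiner).
#' @param refiner function `(patch, predicted mask, index)` returning a
#'   corrected mask.
#' @param epochs fine-tuning epochs for the round (default 4).
#' @return a new `seg_checkpoint` with `stage = "cascade"`, carrying
#'   `accuracy_proxy` (mean Dice) and `skipped` in its `cascade_log`.
#' @export
cascade_round <- function(ckpt, group, refiner, epochs = 4L) {
  stopifnot(inherits(ckpt, "seg_checkpoint"))
  refined <- vector("list", length(group$patches))
  dices <- numeric(0)
  skipped <- integer(0)
  for (i in seq_along(group$patches)) {
    p <- group$patches[[i]]
    pm <- predict_mask(ckpt, p$pixels)
    res <- tryCatch(refiner(p$pixels, pm$mask, i), error = function(e) e)
    if (inherits(res, "error")) {
      skipped <- c(skipped, i)
      next
    }
    refined[[i]] <- res
    dices <- c(dices, dice_coef(pm$mask, res))
  }
  keep <- which(!vapply(refined, is.null, TRUE))
  if (length(keep) == 0L) stop("refiner failed on every patch in the group")
  acc <- mean(dices)

  # retrain on the refined masks, starting from the current weights
  ref_set <- group
  ref_set$patches <- lapply(keep, function(i) group$patches[[i]])
  ref_masks <- refined[keep]
  new <- train_on_masks(ckpt, ref_set, ref_masks, epochs)
  new$stage <- "cascade"
  new$cascade_log <- list(accuracy_proxy = acc, skipped = skipped,
                          n_used = length(keep))
  new
}

# internal: fine-tune on explicit masks (not center-derived)
train_on_masks <- function(ckpt, aps, masks, epochs) {
  config <- ckpt$config
  params <- ckpt$params
  mstate <- lapply(params, function(p) p * 0)
  vstate <- lapply(params, function(p) p * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L
  n <- length(aps$patches)
  log <- ckpt$log
  for (ep in seq_len(epochs)) {
    ord <- with_seed(derive_seed(config$seed, paste0("cascade_shuffle", ep)),
                     sample.int(n))
    ep_loss <- 0
    acc <- NULL; acc_n <- 0L
    for (ii in seq_along(ord)) {
      i <- ord[ii]
      aug <- augment(aps$patches[[i]]$pixels, masks[[i]],
                     seed = derive_seed(config$seed,
                                        sprintf("caug%d_%d", ep, i)),
                     crop_size = min(config$crop_size,
                                     dim(aps$patches[[i]]$pixels)[1]))
      lg <- cpp_unet_loss_grad(params, patch_to_cube(aug$patch),
                               aug$mask * 1, config$widths, config$in_ch,
                               config$loss)
      if (!is.finite(lg$loss)) stop("cascade fine-tuning diverged")
      ep_loss <- ep_loss + lg$loss
      acc <- if (is.null(acc)) lg$grads else Map(`+`, acc, lg$grads)
      acc_n <- acc_n + 1L
      if (acc_n == config$batch_size || ii == n) {
        step <- step + 1L
        for (nm in names(params)) {
          g <- acc[[nm]] / acc_n
          mstate[[nm]] <- b1 * mstate[[nm]] + (1 - b1) * g
          vstate[[nm]] <- b2 * vstate[[nm]] + (1 - b2) * g^2
          params[[nm]] <- params[[nm]] - config$lr *
            (mstate[[nm]] / (1 - b1^step)) /
            (sqrt(vstate[[nm]] / (1 - b2^step)) + eps)
        }
        acc <- NULL; acc_n <- 0L
      }
    }
    log <- rbind(log, data.frame(epoch = max(log$epoch %||% 0, 0) + ep,
                                 train_loss = ep_loss / n, val_loss = NA))
  }
  structure(list(params = params, config = config, log = log,
                 stage = ckpt$stage), class = "seg_checkpoint")
}

#' Run the full cascade-training loop
#'
#' Applies [cascade_round()] on successive groups until the accuracy proxy
#' reaches `stop_dice` or `max_rounds` rounds have run (two rounds is the
#' reference protocol).
#'
#' @param ckpt starting checkpoint (the model trained on the initial set).
#' @param groups list of `annotated_patches` groups, one per round
#'   (recycled if fewer than `max_rounds`).
#' @param refiner see [cascade_round()].
#' @param max_rounds maximum rounds (default 2).
#' @param stop_dice stop when the pre-round accuracy proxy reaches this
#'   (default 0.9).
#' @param epochs fine-tuning epochs per round.
#' @return final `seg_checkpoint` (stage `"U2"`), with `rounds_run` and the
#'   per-round accuracy proxies attached.
#' @export
cascade_train <- function(ckpt, groups, refiner, max_rounds = 2L,
                          stop_dice = 0.9, epochs = 4L) {
  if (!is.list(groups) || inherits(groups, "annotated_patches")) {
    groups <- list(groups)
  }
  proxies <- numeric(0)
  rounds <- 0L
  for (r in seq_len(max_rounds)) {
    grp <- groups[[(r - 1L) %% length(groups) + 1L]]
    new <- cascade_round(ckpt, grp, refiner, epochs = epochs)
    proxies <- c(proxies, new$cascade_log$accuracy_proxy)
    # the proxy is measured on predictions made *before* the round's
    # retraining: if the model already met the bar, keep it and stop
    if (new$cascade_log$accuracy_proxy >= stop_dice) {
      ckpt$stage <- "U2"
      ckpt$rounds_run <- rounds
      ckpt$accuracy_proxies <- proxies
      return(ckpt)
    }
    ckpt <- new
    rounds <- r
  }
  ckpt$stage <- "U2"
  ckpt$rounds_run <- rounds
  ckpt$accuracy_proxies <- proxies
  ckpt
}

#' Save / load a checkpoint
#'
#' Weights go to a single binary file with a JSON sidecar carrying the
#' config, stage and training log.
#'
#' @param ckpt a `seg_checkpoint`.
#' @param path base path (`.rds` + `.json` are appended).
#' @return `path` (save) / the checkpoint (load).
#' @export
save_checkpoint <- function(ckpt, path) {
  saveRDS(ckpt, paste0(path, ".rds"))
  jsonlite::write_json(list(stage = ckpt$stage,
                            config = unclass(ckpt$config),
                            log = ckpt$log),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ckpt <- readRDS(paste0(path, ".rds"))
  stopifnot(inherits(ckpt, "seg_checkpoint"))
  ckpt
}
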