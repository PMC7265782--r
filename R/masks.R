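# Mask construction from point annotations, geometric augmentation, and
# cell-level detection evaluation.

#' Dilate annotated centers into a binary disc mask
#'
#' Each center is dilated into a circular area (diameter 32 px by default,
#' the size of a lymphocyte nucleus at 40x). Disc membership is
#' `||p - c|| <= diameter/2` evaluated on pixel centers; overlapping discs
#' merge; discs are clipped at the image border.
#'
#' @param centers numeric matrix of `(row, col)` centers (0-based), possibly
#'   empty.
#' @param shape `(rows, cols)` of the output mask.
#' @param diameter disc diameter in pixels (>= 1, default 32).
#' @return logical matrix.
#' @export
centers_to_mask <- function(centers, shape, diameter = 32) {
  if (diameter < 1) stop("diameter must be >= 1")
  m <- matrix(0, shape[1], shape[2])
  if (!is.null(centers) && NROW(centers) > 0) {
    centers <- matrix(as.numeric(centers), ncol = 2)
    m <- cpp_paint_discs(m, centers, diameter / 2, 1)
  }
  m > 0
}

#' Jointly augment a patch and its mask
#'
#' Random mirror (horizontal and/or vertical) and random crop, the identical
#' geometric transform applied to both patch and mask; reproducible for a
#' fixed seed.
#'
#' @param patch `[rows, cols, 3]` array.
#' @param mask logical/numeric matrix aligned with `patch`.
#' @param seed RNG seed.
#' @param crop_size side of the random square crop; `NULL` disables
#'   cropping. Must not exceed the patch.
#' @param mirror apply random mirroring (default TRUE).
#' @return `list(patch = , mask = )`.
#' @export
augment <- function(patch, mask, seed, crop_size = NULL, mirror = TRUE) {
  d <- dim(patch)
  stopifnot(all(dim(mask) == d[1:2]))
  if (!is.null(crop_size) && (crop_size > d[1] || crop_size > d[2])) {
    stop("crop size exceeds patch size")
  }
  with_seed(seed, {
    if (mirror) {
      if (runif(1) < 0.5) { # horizontal mirror: reverse columns
        patch <- patch[, d[2]:1, , drop = FALSE]
        mask <- mask[, d[2]:1, drop = FALSE]
      }
      if (runif(1) < 0.5) { # vertical mirror: reverse rows
        patch <- patch[d[1]:1, , , drop = FALSE]
        mask <- mask[d[1]:1, , drop = FALSE]
      }
    }
    if (!is.null(crop_size)) {
      r0 <- sample.int(d[1] - crop_size + 1L, 1L)
      c0 <- sample.int(d[2] - crop_size + 1L, 1L)
      patch <- patch[r0:(r0 + crop_size - 1L), c0:(c0 + crop_size - 1L), ,
                     drop = FALSE]
      mask <- mask[r0:(r0 + crop_size - 1L), c0:(c0 + crop_size - 1L),
                   drop = FALSE]
    }
    list(patch = patch, mask = mask)
  })
}

#' Reduce a binary mask to detected cell centers
#'
#' Connected components (8-connectivity) with area at least `min_area`
#' (default 80 px, about 10% of a 32-px disc) are reduced to their
#' centroids. Overlapping nuclei merged into one component yield a single
#' centroid - a documented limitation.
#'
#' @param mask logical matrix.
#' @param min_area minimum component pixel count.
#' @return numeric matrix of `(row, col)` centroids (0-based).
#' @export
extract_detections <- function(mask, min_area = 80) {
  labs <- cpp_label_components(mask, 8L)
  if (max(labs) == 0L) return(matrix(0, 0, 2))
  idx <- which(labs > 0L, arr.ind = TRUE)
  lab <- labs[labs > 0L]
  sizes <- tabulate(lab)
  keep <- which(sizes >= min_area)
  if (length(keep) == 0L) return(matrix(0, 0, 2))
  rs <- vapply(keep, function(l) mean(idx[lab == l, 1]) - 1, 0)
  cs <- vapply(keep, function(l) mean(idx[lab == l, 2]) - 1, 0)
  cbind(rs, cs, deparse.level = 0)
}

#' Match predicted and ground-truth cell centers and score detection
#'
#' One-to-one greedy matching by ascending distance (ties by prediction
#' index, then truth index) within `radius`; each truth center is matched at
#' most once. Matched pairs are true positives, unmatched predictions false
#' positives, unmatched truths false negatives. With no predictions,
#' precision is reported as 0 with `precision_undefined = TRUE`.
#'
#' @param pred,truth numeric matrices of `(row, col)` centers.
#' @param radius matching radius in pixels (default 16, half the nominal
#'   32-px nucleus diameter).
#' @return object of class `detection_result` with counts, index pairs and
#'   precision/recall/F1.
#' @export
evaluate_detections <- function(pred, truth, radius = 16) {
  if (radius <= 0) stop("radius must be > 0")
  pred <- matrix(as.numeric(pred), ncol = 2)
  truth <- matrix(as.numeric(truth), ncol = 2)
  np <- nrow(pred); nt <- nrow(truth)
  matches <- matrix(0L, 0, 2)
  if (np > 0 && nt > 0) {
    dmat <- sqrt(outer(pred[, 1], truth[, 1], `-`)^2 +
                 outer(pred[, 2], truth[, 2], `-`)^2)
    cand <- which(dmat <= radius, arr.ind = TRUE)
    if (nrow(cand) > 0) {
      ord <- order(dmat[cand], cand[, 1], cand[, 2])
      cand <- cand[ord, , drop = FALSE]
      used_p <- logical(np); used_t <- logical(nt)
      for (i in seq_len(nrow(cand))) {
        p <- cand[i, 1]; t <- cand[i, 2]
        if (!used_p[p] && !used_t[t]) {
          used_p[p] <- TRUE; used_t[t] <- TRUE
          matches <- rbind(matches, c(p, t))
        }
      }
    }
  }
  tp <- nrow(matches)
  fp <- np - tp
  fn <- nt - tp
  precision_undefined <- np == 0L
  precision <- if (np == 0L) 0 else tp / np
  recall <- if (nt == 0L) 1 else tp / nt
  f1 <- if (precision + recall == 0) 0 else {
    2 * precision * recall / (precision + recall)
  }
  structure(list(tp = tp, fp = fp, fn = fn,
                 matches = matches,
                 fp_idx = setdiff(seq_len(np), matches[, 1]),
                 fn_idx = setdiff(seq_len(nt), matches[, 2]),
                 precision = precision, recall = recall, f1 = f1,
                 precision_undefined = precision_undefined,
                 radius = radius),
            class = "detection_result")
}

#' @method print detection_result
#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf("<detection: TP %d FP %d FN %d | P %.4f R %.4f F1 %.4f>\n",
              x$tp, x$fp, x$fn, x$precision, x$recall, x$f1))
  invisible(x)
}
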