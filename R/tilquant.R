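# Tiling of the field of view, global TIL map assembly, and the TIL score:
# the fraction of tissue pixels predicted lymphocytic over all valid
# patches, TIL% = sum(L_i) / sum(T_i).

#' Tile a field-of-view crop into fixed-size patches
#'
#' The crop is split into nonoverlapping `patch_size` x `patch_size` patches
#' (row-major); partial edge patches are dropped. A patch is valid when its
#' background fraction is at most `max_background` (default 0.8). The
#' background map reuses the field-of-view K-means classes, mapped to full
#' resolution, when a `fov_region` is given; otherwise the crop is
#' re-clustered at full resolution.
#'
#' @param crop integer `[rows, cols, 3]` full-resolution RGB array.
#' @param patch_size patch side in pixels (default 200).
#' @param fov optional `fov_region` from [identify_fov()] (its low-res
#'   cluster labels are upscaled into the crop).
#' @param max_background maximum background fraction for a valid patch.
#' @param k,seed clustering parameters used when `fov` is absent.
#' @return object of class `patch_grid`: data frame `entries` with
#'   `grid_row, grid_col, r0, c0, background_fraction, valid`, plus
#'   `patch_size`, `K` (valid patch count) and the full-resolution
#'   `tissue_mask` of the crop.
#' @export
tile_fov <- function(crop, patch_size = 200L, fov = NULL,
                     max_background = 0.8, k = 3L, seed = 1L) {
  d <- dim(crop)
  if (d[1] < patch_size || d[2] < patch_size) {
    warning("crop smaller than one patch; using a single clipped patch")
    patch_size <- min(d[1], d[2])
  }
  tissue <- crop_tissue_mask(crop, fov, k = k, seed = seed)
  nr <- d[1] %/% patch_size
  nc <- d[2] %/% patch_size
  entries <- expand.grid(grid_col = seq_len(nc) - 1L,
                         grid_row = seq_len(nr) - 1L)[, 2:1]
  entries$r0 <- entries$grid_row * patch_size
  entries$c0 <- entries$grid_col * patch_size
  entries$background_fraction <- vapply(seq_len(nrow(entries)), function(i) {
    rs <- entries$r0[i] + seq_len(patch_size)
    cs <- entries$c0[i] + seq_len(patch_size)
    1 - mean(tissue[rs, cs])
  }, 0)
  entries$valid <- entries$background_fraction <= max_background
  structure(list(entries = entries, patch_size = as.integer(patch_size),
                 K = sum(entries$valid), tissue_mask = tissue,
                 crop_dim = d[1:2]),
            class = "patch_grid")
}

# full-resolution tissue mask for a crop, reusing the FOV cluster labels
# when available (nearest-neighbour upscaling of the low-res label map)
crop_tissue_mask <- function(crop, fov = NULL, k = 3L, seed = 1L) {
  d <- dim(crop)
  if (is.null(fov)) {
    cl <- cluster_tissue(array(as.double(crop), d), k = k, seed = seed)
    return(cl$tissue_mask)
  }
  f <- fov$factor
  b <- fov$bbox_full
  # rows/cols of the crop in full-res slide coords -> low-res label indices
  rows_full <- b[["r0"]] + seq_len(d[1]) - 1L
  cols_full <- b[["c0"]] + seq_len(d[2]) - 1L
  low_r <- pmin(rows_full %/% f + 1L, nrow(fov$labels_low))
  low_c <- pmin(cols_full %/% f + 1L, ncol(fov$labels_low))
  fov$labels_low[low_r, low_c] != fov$background_label
}

#' @method print patch_grid
#' @export
print.patch_grid <- function(x, ...) {
  cat(sprintf("<patch_grid: %d patches (%d valid) of %dpx>\n",
              nrow(x$entries), x$K, x$patch_size))
  invisible(x)
}

#' Compute the global TIL map of a crop
#'
#' Runs the segmentation model on every valid patch. Per valid patch i,
#' `L_i` is the count of predicted lymphocyte pixels intersected with
#' tissue and `T_i` the count of tissue pixels; the visualization level is
#' `round(250 * L_i / T_i)`. Patch predictions are stitched into one binary
#' mask at their offsets. Invalid patches are skipped, not scored.
#'
#' @param ckpt a `seg_checkpoint`.
#' @param grid a `patch_grid` from [tile_fov()].
#' @param crop the same crop the grid was built from.
#' @return object of class `til_map`: `entries` data frame gains `Li, Ti,
#'   level`; plus the stitched logical `mask`.
#' @export
compute_til_map <- function(ckpt, grid, crop) {
  stopifnot(inherits(grid, "patch_grid"))
  ps <- grid$patch_size
  ent <- grid$entries
  ent$Li <- NA_real_; ent$Ti <- NA_real_; ent$level <- NA_integer_
  stitched <- matrix(FALSE, grid$crop_dim[1], grid$crop_dim[2])
  for (i in seq_len(nrow(ent))) {
    if (!ent$valid[i]) next
    rs <- ent$r0[i] + seq_len(ps)
    cs <- ent$c0[i] + seq_len(ps)
    tis <- grid$tissue_mask[rs, cs]
    pm <- predict_mask(ckpt, crop[rs, cs, , drop = FALSE])
    lym <- pm$mask & tis
    ent$Li[i] <- sum(lym)
    ent$Ti[i] <- sum(tis)
    ent$level[i] <- if (ent$Ti[i] > 0) as.integer(round(250 * ent$Li[i] / ent$Ti[i])) else 0L
    stitched[rs, cs] <- lym
  }
  structure(list(entries = ent, patch_size = ps, K = grid$K,
                 mask = stitched, crop_dim = grid$crop_dim),
            class = "til_map")
}

#' @method print til_map
#' @export
print.til_map <- function(x, ...) {
  cat(sprintf("<til_map: %d valid patches, TIL%% = %.4f>\n", x$K,
              tryCatch(til_score(x), error = function(e) NA)))
  invisible(x)
}

#' The slide-level TIL score
#'
#' The exact ratio of sums `sum(L_i) / sum(T_i)` over valid patches - not
#' the mean of per-patch ratios.
#'
#' @param map a `til_map`, or a list/data frame with `Li` and `Ti` vectors.
#' @return numeric fraction in `[0, 1]`.
#' @export
til_score <- function(map) {
  ent <- if (inherits(map, "til_map")) {
    map$entries[map$entries$valid, , drop = FALSE]
  } else {
    as.data.frame(map)
  }
  if (nrow(ent) == 0L) stop("no tissue: the map has no valid patches")
  sT <- sum(ent$Ti); sL <- sum(ent$Li)
  if (sT <= 0) stop("no tissue: total tissue pixel count is zero")
  sL / sT
}

#' Serialize / restore a TIL map
#'
#' CSV of `grid_row, grid_col, Li, Ti, level` for valid patches (missing
#' entries preserved as NA), with a metadata header.
#'
#' @param map a `til_map`.
#' @param path output CSV path.
#' @param seed recorded in the metadata header.
#' @return `path` / a reconstructed `til_map` (without the stitched mask).
#' @export
write_til_map <- function(map, path, seed = NULL) {
  ent <- map$entries[, c("grid_row", "grid_col", "Li", "Ti", "level", "valid")]
  write_csv_meta(ent, path, seed = seed,
                 extra = list(patch_size = map$patch_size,
                              crop_rows = map$crop_dim[1],
                              crop_cols = map$crop_dim[2]))
}

#' @rdname write_til_map
#' @export
read_til_map <- function(path) {
  ent <- tryCatch(read_csv_meta(path), error = function(e) {
    stop("malformed TIL map ", path, ": ", conditionMessage(e))
  })
  need <- c("grid_row", "grid_col", "Li", "Ti", "level", "valid")
  miss <- setdiff(need, names(ent))
  if (length(miss)) {
    stop("malformed TIL map ", path, ": missing field(s) ",
         paste(miss, collapse = ", "))
  }
  hdr <- readLines(path, n = 10)
  getf <- function(key, default) {
    ln <- grep(paste0("^# ", key, ": "), hdr, value = TRUE)
    if (length(ln)) as.integer(sub(".*: ", "", ln[1])) else default
  }
  ps <- getf("patch_size", 200L)
  structure(list(entries = ent, patch_size = ps,
                 K = sum(ent$valid), mask = NULL,
                 crop_dim = c(getf("crop_rows", NA), getf("crop_cols", NA))),
            class = "til_map")
}

#' Write the TIL map as a color heatmap (PNG)
#'
#' Patch levels 0..250 are mapped blue (no TIL) through red (all TIL).
#' Requires the grDevices PNG device; silently skipped when unavailable.
#'
#' @param map a `til_map`.
#' @param path output PNG path.
#' @return `path` invisibly (or `NULL` when skipped).
#' @export
write_til_heatmap <- function(map, path) {
  if (!isTRUE(capabilities("png"))) return(invisible(NULL))
  ent <- map$entries
  nr <- max(ent$grid_row) + 1L; nc <- max(ent$grid_col) + 1L
  lvl <- matrix(NA_real_, nr, nc)
  lvl[cbind(ent$grid_row + 1L, ent$grid_col + 1L)] <- ent$level
  pal <- grDevices::colorRampPalette(c("blue", "cyan", "yellow", "red"))(251)
  img <- matrix("#FFFFFF", nr, nc)
  ok <- !is.na(lvl)
  img[ok] <- pal[pmin(lvl[ok], 250) + 1]
  grDevices::png(path, width = nc * 8, height = nr * 8)
  op <- graphics::par(mar = c(0, 0, 0, 0))
  graphics::plot.new()
  graphics::rasterImage(img, 0, 0, 1, 1, interpolate = FALSE)
  graphics::par(op)
  grDevices::dev.off()
  invisible(path)
}
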