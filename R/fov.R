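# Field-of-view identification: the slide is downsampled (16:1 by default),
# converted to CIELAB, pixels are K-means-clustered into three groups, the
# cluster containing the upper-left corner pixel is declared background
# (slide corners are typically unstained), and the smallest rectangle
# containing the largest connected tissue component is mapped back to full
# resolution.

#' Downsample an RGB raster by block averaging
#'
#' Output dimensions are `ceiling(input / factor)`; `factor = 1` is the
#' identity.
#'
#' @param slide a [raster_slide] or `[rows, cols, 3]` array.
#' @param factor integer >= 1.
#' @return numeric `[rows', cols', 3]` array.
#' @export
downsample <- function(slide, factor) {
  if (factor < 1) stop("downsample factor must be >= 1")
  px <- if (inherits(slide, "raster_slide")) slide$pixels else slide
  out <- cpp_block_downsample(array(as.double(px), dim(px)), as.integer(factor))
  array(out, dim(out))
}

rgb_to_lab <- function(px) {
  # sRGB (0..255) -> CIELAB, D65 white point
  m <- cbind(as.vector(px[, , 1]), as.vector(px[, , 2]),
             as.vector(px[, , 3])) / 255
  grDevices::convertColor(m, from = "sRGB", to = "Lab")
}

#' Cluster slide pixels into background and tissue
#'
#' K-means (default k = 3) in CIELAB space; the background label is the
#' cluster of the upper-left corner pixel, all other clusters are treated as
#' tissue (tumor or stroma).
#'
#' @param image numeric `[rows, cols, 3]` RGB array (typically downsampled).
#' @param k number of clusters (>= 2; default 3).
#' @param seed RNG seed for the K-means initialization.
#' @param nstart K-means restarts (default 5).
#' @return `list(labels = integer matrix, background_label = integer,
#'   tissue_mask = logical matrix)`.
#' @export
cluster_tissue <- function(image, k = 3L, seed = 1L, nstart = 5L) {
  if (k < 2) stop("k must be >= 2")
  lab <- rgb_to_lab(image)
  h <- dim(image)[1]; w <- dim(image)[2]
  uniq <- unique(round(lab, 6))
  if (nrow(uniq) < k) {
    warning(sprintf("only %d distinct colors for k = %d; assigning by color",
                    nrow(uniq), k))
    key <- apply(round(lab, 6), 1, paste, collapse = ",")
    labels <- matrix(as.integer(factor(key)), h, w)
  } else {
    km <- with_seed(seed, kmeans(lab, centers = k, nstart = nstart,
                                 iter.max = 50))
    labels <- matrix(km$cluster, h, w)
  }
  bg <- labels[1, 1]
  tissue <- labels != bg
  if (mean(!tissue) > 0.95 && all(!tissue) == FALSE) {
    warning("corner-pixel cluster covers >95% of the image; slide may be unstained")
  }
  list(labels = labels, background_label = bg, tissue_mask = tissue)
}

#' Tight bounding box of the largest connected mask component
#'
#' Ties in component size are broken toward the component whose first pixel
#' in row-major scan order comes first.
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8 (default 8).
#' @return a half-open [til_box], or `NULL` for an empty mask.
#' @export
largest_tissue_bbox <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask))
  labs <- cpp_label_components(mask, as.integer(connectivity))
  if (max(labs) == 0L) return(NULL)
  tab <- tabulate(labs[labs > 0L])
  best <- which.max(tab) # labels are assigned in row-major discovery order
  idx <- which(labs == best, arr.ind = TRUE)
  til_box(min(idx[, 1]) - 1L, min(idx[, 2]) - 1L, max(idx[, 1]), max(idx[, 2]))
}

#' Identify the field of view of a slide
#'
#' Composition of [downsample()], [cluster_tissue()] and
#' [largest_tissue_bbox()]; the low-resolution box is scaled by the
#' downsample factor and clipped to the slide bounds.
#'
#' @param slide a [raster_slide].
#' @param factor downsample factor (default the slide's, normally 16).
#' @param k,seed,connectivity passed to the clustering / labeling steps.
#' @return object of class `fov_region`: `list(bbox_low, bbox_full,
#'   tissue_mask_low, factor, background_label)`.
#' @export
identify_fov <- function(slide, factor = NULL, k = 3L, seed = 1L,
                         connectivity = 8L) {
  stopifnot(inherits(slide, "raster_slide"))
  factor <- as.integer(factor %||% slide$downsample_factor)
  low <- downsample(slide, factor)
  cl <- cluster_tissue(low, k = k, seed = seed)
  bbox_low <- largest_tissue_bbox(cl$tissue_mask, connectivity)
  if (is.null(bbox_low)) {
    stop("no tissue detected: the whole slide clusters with the corner pixel")
  }
  d <- dim(slide$pixels)
  structure(list(
    bbox_low = bbox_low,
    bbox_full = scale_box(bbox_low, factor, d[1], d[2]),
    tissue_mask_low = cl$tissue_mask,
    factor = factor,
    background_label = cl$background_label,
    labels_low = cl$labels
  ), class = "fov_region")
}

#' @method print fov_region
#' @export
print.fov_region <- function(x, ...) {
  cat("<fov_region>\n  low: "); print(x$bbox_low)
  cat("  full:"); print(x$bbox_full)
  invisible(x)
}

#' Crop the full-resolution field of view from a slide
#' @param slide a [raster_slide].
#' @param fov a `fov_region` from [identify_fov()].
#' @return integer `[rows, cols, 3]` array.
#' @export
crop_fov <- function(slide, fov) {
  b <- fov$bbox_full
  slide$pixels[(b[["r0"]] + 1):b[["r1"]], (b[["c0"]] + 1):b[["c1"]], ,
               drop = FALSE]
}

#' Serialize a field-of-view region to JSON
#' @param fov a `fov_region`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_fov <- function(fov, path) {
  jsonlite::write_json(list(
    bbox_low = as.integer(fov$bbox_low),
    bbox_full = as.integer(fov$bbox_full),
    factor = fov$factor
  ), path, auto_unbox = TRUE)
  invisible(path)
}
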