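# Annotated training patches: 200x200 tissue-filled tiles with lymphocyte
# center annotations, mimicking the geometry of public lymphocyte-detection
# sets (200 images of 200x200 px at 40x with expert center points).

#' Generate a set of annotated 200x200 patches
#'
#' Each patch is fully covered by tissue stain, with Poisson-count
#' lymphocyte nuclei (clustered + uniform placement per the spec) and
#' optional distractor nuclei. Centers are annotated exactly where nuclei
#' are rendered. `role` tweaks the placement to emulate the two kinds of
#' cascade-training patches: `"hotspot"` (3x density, fully clustered) and
#' `"scattered"` (base density, no clustering); `"d1"` uses the spec as-is.
#'
#' @param n number of patches (> 0).
#' @param spec a [slide_spec]; `width`/`height` are ignored (patches are
#'   `patch_size` square), all nucleus parameters are honoured.
#' @param role one of `"d1"`, `"hotspot"`, `"scattered"`, or `"mixed"`
#'   (half hotspot / half scattered, as in cascade groups).
#' @param patch_size patch side in pixels (default 200).
#' @param seed RNG seed; defaults to `spec$seed`.
#' @return object of class `annotated_patches`: list with `patches` (each
#'   `list(pixels, centers)`, centers 0-based `(row, col)`), `role`,
#'   `patch_size`, `seed`.
#' @export
generate_annotated_patches <- function(n, spec, role = "d1",
                                       patch_size = 200L, seed = NULL) {
  stopifnot(inherits(spec, "slide_spec"), n > 0)
  role <- match.arg(role, c("d1", "hotspot", "scattered", "mixed"))
  seed <- seed %||% spec$seed
  roles <- switch(role,
    d1 = rep("d1", n),
    hotspot = rep("hotspot", n),
    scattered = rep("scattered", n),
    # cascade groups: 50% immune hotspots, 50% scattered tissue
    mixed = rep(c("hotspot", "scattered"), length.out = n)
  )
  tissue_color <- spec$tissue_blobs[[1]]$color
  r_lymph <- spec$lymph_diameter / 2
  area <- as.double(patch_size)^2
  with_seed(seed, {
    patches <- lapply(seq_len(n), function(i) {
      rl <- roles[i]
      density <- spec$lymph_density * switch(rl, hotspot = 3, 1)
      cfrac <- switch(rl, hotspot = 1, scattered = 0, spec$cluster_fraction)
      n_l <- rpois(1, density * area)
      centers <- place_patch_points(n_l, patch_size, cfrac, spec)
      n_d <- rpois(1, spec$distractor_density * area)
      dis <- cbind(runif(n_d, 0, patch_size - 1), runif(n_d, 0, patch_size - 1))

      px <- array(0, c(patch_size, patch_size, 3))
      for (ch in 1:3) {
        px[, , ch] <- tissue_color[ch]
      }
      if (n_d > 0L) {
        px <- paint_ellipses(px, dis, cbind(runif(n_d, 16, 24),
                                            runif(n_d, 16, 24)),
                             spec$distractor_color)
      }
      px <- paint_rgb_discs(px, centers, r_lymph, spec$lymph_color)
      if (spec$noise_sd > 0) {
        px <- px + array(rnorm(length(px), sd = spec$noise_sd), dim(px))
      }
      storage.mode(px) <- "integer"
      px <- pmin(pmax(px, 0L), 255L)
      list(pixels = px, centers = centers, role = rl)
    })
    structure(list(patches = patches, role = role,
                   patch_size = as.integer(patch_size),
                   lymph_diameter = spec$lymph_diameter, seed = seed),
              class = "annotated_patches")
  })
}

# clustered/uniform placement inside a square patch (0-based coords), with
# the same hard-core minimum separation as slide-level placement
place_patch_points <- function(n, size, cluster_fraction, spec) {
  if (n == 0L) return(matrix(0, 0, 2))
  n_clust <- round(n * cluster_fraction)
  n_parents <- max(1L, round(max(n_clust, 1) / spec$cluster_size))
  parents <- cbind(runif(n_parents, 0, size - 1), runif(n_parents, 0, size - 1))
  assign_p <- if (n_clust > 0L) {
    sample.int(n_parents, n_clust, replace = TRUE)
  } else integer(0)
  acc <- matrix(0, n, 2)
  n_acc <- 0L
  for (i in seq_len(n)) {
    clustered <- i <= n_clust
    ok <- FALSE
    # clustered candidates fall back to uniform after 30 tries so dense
    # hotspots lose as little intensity as possible
    for (try in 1:60) {
      cand <- if (clustered && try <= 30) {
        p <- parents[assign_p[i], ] + rnorm(2, sd = spec$cluster_sd / 2)
        pmin(pmax(p, 0), size - 1)
      } else {
        runif(2, 0, size - 1)
      }
      if (respects_core(cand, acc, n_acc, spec$min_separation)) {
        ok <- TRUE
        break
      }
    }
    if (ok) {
      n_acc <- n_acc + 1L
      acc[n_acc, ] <- cand
    }
  }
  acc[seq_len(n_acc), , drop = FALSE]
}

#' @method print annotated_patches
#' @export
print.annotated_patches <- function(x, ...) {
  cat(sprintf("<annotated_patches: %d patches of %dx%d, role '%s', %d centers>\n",
              length(x$patches), x$patch_size, x$patch_size, x$role,
              sum(vapply(x$patches, function(p) nrow(p$centers), 0L))))
  invisible(x)
}

#' Reproducible train/test split of an annotated patch set
#'
#' @param aps an `annotated_patches` object.
#' @param train_fraction fraction assigned to training (default 0.8, the
#'   conventional 160/40 split for a 200-patch set).
#' @param seed RNG seed for the permutation.
#' @return `list(train = , test = )`, both `annotated_patches`, disjoint.
#' @export
split_patches <- function(aps, train_fraction = 0.8, seed = 1L) {
  stopifnot(inherits(aps, "annotated_patches"),
            train_fraction > 0, train_fraction < 1)
  n <- length(aps$patches)
  n_train <- round(n * train_fraction)
  idx <- with_seed(seed, sample.int(n))
  mk <- function(ii) {
    out <- aps
    out$patches <- aps$patches[ii]
    out
  }
  list(train = mk(sort(idx[seq_len(n_train)])),
       test = mk(sort(idx[-seq_len(n_train)])))
}

#' Write patch annotations as center CSVs
#'
#' One `row,col` CSV per patch plus the patch rasters as PPM, following the
#' point-annotation convention of public lymphocyte datasets.
#'
#' @param aps an `annotated_patches` object.
#' @param dir output directory (created if needed).
#' @return vector of written paths, invisibly.
#' @export
write_patches <- function(aps, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (i in seq_along(aps$patches)) {
    p <- aps$patches[[i]]
    img <- file.path(dir, sprintf("patch_%03d.ppm", i))
    ann <- file.path(dir, sprintf("patch_%03d_centers.csv", i))
    write_slide(p$pixels, img)
    df <- as.data.frame(p$centers)
    names(df) <- c("row", "col")
    write_csv_meta(df, ann)
    paths <- c(paths, img, ann)
  }
  invisible(paths)
}

#' Read a patch-annotation CSV, validating bounds
#'
#' @param path CSV with `row,col` columns (0-based pixel coordinates).
#' @param shape `(rows, cols)` of the patch the annotations belong to.
#' @return numeric matrix of centers.
#' @export
read_centers <- function(path, shape = NULL) {
  df <- read_csv_meta(path)
  if (!all(c("row", "col") %in% names(df))) {
    stop("annotation file ", path, " lacks row,col columns")
  }
  m <- cbind(df$row, df$col)
  if (!is.null(shape) && nrow(m) > 0) {
    bad <- m[, 1] < 0 | m[, 1] > shape[1] - 1 | m[, 2] < 0 | m[, 2] > shape[2] - 1
    if (any(bad)) {
      stop(sprintf("annotation file %s: %d center(s) outside %dx%d bounds (first at line %d)",
                   path, sum(bad), shape[1], shape[2], which(bad)[1]))
    }
  }
  m
}
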