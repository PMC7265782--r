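# Synthetic stained-slide generator: one or more roughly circular tissue
# blobs of eosin-like stain on a near-white background, with round dark
# hematoxylin-like lymphocyte nuclei scattered and clustered inside the
# tissue, plus optional larger/paler distractor nuclei. All geometry is at
# nominal 40x (a lymphocyte of ~8 um is ~32 px across).

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Specification for a synthetic slide
#'
#' @param width,height canvas size in pixels at nominal 40x.
#' @param tissue_blobs list of blobs, each `list(center = c(row, col),
#'   radius, color = c(r, g, b))`; defaults to one central blob filling most
#'   of the canvas.
#' @param lymph_density expected lymphocytes per tissue pixel (a 200x200
#'   fully tissue patch then carries `4e4 * lymph_density` nuclei on
#'   average). Default `2e-4` (~8 nuclei per patch).
#' @param lymph_diameter lymphocyte nucleus diameter in pixels (default 32,
#'   i.e. ~8 um at 40x).
#' @param cluster_fraction fraction of nuclei placed in spatial clusters
#'   (parent/offspring process) rather than uniformly; default 0.5.
#' @param cluster_sd spatial spread (px) of offspring around a cluster
#'   parent; default 65.
#' @param cluster_size mean nuclei per cluster parent; default 12.
#' @param min_separation hard-core minimum distance between nucleus centers
#'   (px); nuclei are solid bodies, so centers cannot approach closer than
#'   about one diameter. Default `1.1 * lymph_diameter`. Candidates violating
#'   the constraint are re-drawn (Matern-II-style thinning), so realized
#'   counts can fall slightly below the nominal Poisson draw in very dense
#'   clusters.
#' @param distractor_density expected non-lymphocyte nuclei (larger, paler
#'   ellipses) per tissue pixel; default `0.3 * lymph_density`.
#' @param background_color,lymph_color,distractor_color RGB triplets.
#' @param noise_sd additive Gaussian RGB noise scale (default 4).
#' @param seed RNG seed.
#' @return object of class `slide_spec`.
#' @export
slide_spec <- function(width = 1600, height = 1600,
                       tissue_blobs = NULL,
                       lymph_density = 2e-4,
                       lymph_diameter = 32,
                       cluster_fraction = 0.5,
                       cluster_sd = 65,
                       cluster_size = 12,
                       min_separation = 1.1 * lymph_diameter,
                       distractor_density = 0.3 * lymph_density,
                       background_color = c(246, 243, 246),
                       lymph_color = c(62, 45, 94),
                       distractor_color = c(172, 138, 188),
                       noise_sd = 4,
                       seed = 1L) {
  assert_scalar_num(width, "width", 1); assert_scalar_num(height, "height", 1)
  assert_scalar_num(lymph_diameter, "lymph_diameter", 4)
  assert_scalar_num(cluster_fraction, "cluster_fraction", 0, 1)
  assert_scalar_num(lymph_density, "lymph_density", 0)
  assert_scalar_num(distractor_density, "distractor_density", 0)
  assert_scalar_num(noise_sd, "noise_sd", 0)
  if (is.null(tissue_blobs)) {
    r <- floor(min(width, height) * 0.35)
    tissue_blobs <- list(list(center = c(height / 2, width / 2), radius = r,
                              color = c(226, 158, 180)))
  }
  for (b in tissue_blobs) {
    stopifnot(length(b$center) == 2, length(b$color) == 3, b$radius > 0)
    if (b$center[1] - b$radius < 0 || b$center[1] + b$radius > height ||
        b$center[2] - b$radius < 0 || b$center[2] + b$radius > width) {
      stop(sprintf(
        "tissue blob at (%g, %g) with radius %g extends outside the %dx%d canvas",
        b$center[1], b$center[2], b$radius, height, width))
    }
  }
  structure(list(
    width = as.integer(width), height = as.integer(height),
    tissue_blobs = tissue_blobs, lymph_density = lymph_density,
    lymph_diameter = lymph_diameter, cluster_fraction = cluster_fraction,
    cluster_sd = cluster_sd, cluster_size = cluster_size,
    min_separation = min_separation,
    distractor_density = distractor_density,
    background_color = background_color, lymph_color = lymph_color,
    distractor_color = distractor_color, noise_sd = noise_sd,
    seed = as.integer(seed)
  ), class = "slide_spec")
}

# sample `n` points uniformly in the union of eligible discs
# (blob radius shrunk by `margin` so that rendered nuclei stay in tissue)
sample_in_blobs <- function(n, blobs, margin) {
  radii <- vapply(blobs, function(b) max(b$radius - margin, 0), 0)
  areas <- pi * radii^2
  if (n == 0L || sum(areas) == 0) return(matrix(0, 0, 2))
  which_blob <- sample.int(length(blobs), n, replace = TRUE, prob = areas)
  rr <- radii[which_blob] * sqrt(runif(n))
  th <- runif(n, 0, 2 * pi)
  ctr <- t(vapply(blobs, function(b) b$center, c(0, 0)))[which_blob, , drop = FALSE]
  cbind(ctr[, 1] + rr * sin(th), ctr[, 2] + rr * cos(th))
}

point_in_blobs <- function(pts, blobs, margin) {
  if (nrow(pts) == 0L) return(logical(0))
  ok <- rep(FALSE, nrow(pts))
  for (b in blobs) {
    r <- max(b$radius - margin, 0)
    ok <- ok | ((pts[, 1] - b$center[1])^2 + (pts[, 2] - b$center[2])^2 <= r^2)
  }
  ok
}

# hard-core acceptance: TRUE when cand keeps min_separation from accepted
respects_core <- function(cand, accepted, n_acc, min_sep) {
  if (n_acc == 0L) return(TRUE)
  d2 <- (accepted[seq_len(n_acc), 1] - cand[1])^2 +
    (accepted[seq_len(n_acc), 2] - cand[2])^2
  all(d2 >= min_sep^2)
}

# clustered (Matern-style parent/offspring with a hard core) + uniform
# placement of n points; candidates that cannot satisfy the hard core after
# 30 tries are dropped (Matern-II thinning)
place_lymphocytes <- function(n, spec, margin) {
  if (n == 0L) return(matrix(0, 0, 2))
  n_clust <- round(n * spec$cluster_fraction)
  n_unif <- n - n_clust
  n_parents <- max(1L, round(max(n_clust, 1) / spec$cluster_size))
  parents <- sample_in_blobs(n_parents, spec$tissue_blobs, margin)
  assign_p <- if (n_clust > 0L) sample.int(n_parents, n_clust, replace = TRUE) else integer(0)
  acc <- matrix(0, n, 2)
  n_acc <- 0L
  for (i in seq_len(n)) {
    clustered <- i <= n_clust
    ok <- FALSE
    # 60 tries; a clustered point that cannot fit near its parent falls
    # back to uniform placement, preserving the Poisson intensity
    for (try in 1:60) {
      cand <- if (clustered && try <= 30) {
        parents[assign_p[i], ] + rnorm(2, sd = spec$cluster_sd)
      } else {
        sample_in_blobs(1, spec$tissue_blobs, margin)[1, ]
      }
      if (clustered && try <= 30 &&
          !point_in_blobs(matrix(cand, 1), spec$tissue_blobs, margin)[1]) next
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

render_tissue_mask <- function(spec) {
  m <- matrix(0, spec$height, spec$width)
  ctrs <- t(vapply(spec$tissue_blobs, function(b) b$center, c(0, 0)))
  for (k in seq_along(spec$tissue_blobs)) {
    m <- cpp_paint_discs(m, ctrs[k, , drop = FALSE],
                         spec$tissue_blobs[[k]]$radius, 1)
  }
  m > 0
}

paint_rgb_discs <- function(px, centers, radius, color) {
  if (nrow(centers) == 0L) return(px)
  for (ch in 1:3) {
    px[, , ch] <- cpp_paint_discs(px[, , ch], centers, radius, color[ch])
  }
  px
}

paint_ellipses <- function(px, centers, axes, color) {
  h <- dim(px)[1]; w <- dim(px)[2]
  for (k in seq_len(nrow(centers))) {
    cr <- centers[k, 1]; cc <- centers[k, 2]
    a <- axes[k, 1]; b <- axes[k, 2]
    rs <- max(0, floor(cr - a)):min(h - 1, ceiling(cr + a))
    cs <- max(0, floor(cc - b)):min(w - 1, ceiling(cc + b))
    inside <- outer((rs - cr)^2 / a^2, (cs - cc)^2 / b^2, `+`) <= 1
    for (ch in 1:3) {
      sub <- px[rs + 1, cs + 1, ch]
      sub[inside] <- color[ch]
      px[rs + 1, cs + 1, ch] <- sub
    }
  }
  px
}

#' Generate a synthetic slide with ground truth
#'
#' Deterministic for a fixed `spec$seed`. Lymphocyte nuclei are filled dark
#' discs of `spec$lymph_diameter`; every rendered nucleus lies fully inside
#' the tissue mask. The expected nucleus count is
#' `lymph_density * (tissue area in px)` (Poisson).
#'
#' @param spec a [slide_spec].
#' @return `list(slide = raster_slide, truth = list(tissue_mask, tissue_bbox,
#'   lymph_centers))`; `tissue_bbox` is the tight half-open box of the
#'   largest connected tissue component, `lymph_centers` a `(row, col)`
#'   matrix (0-based).
#' @export
generate_slide <- function(spec) {
  stopifnot(inherits(spec, "slide_spec"))
  with_seed(spec$seed, {
    r_lymph <- spec$lymph_diameter / 2
    tissue_mask <- render_tissue_mask(spec)
    tissue_area <- sum(tissue_mask)

    n_lymph <- rpois(1, spec$lymph_density * tissue_area)
    centers <- place_lymphocytes(n_lymph, spec, margin = r_lymph)
    n_dis <- rpois(1, spec$distractor_density * tissue_area)
    dis_centers <- sample_in_blobs(n_dis, spec$tissue_blobs, margin = 24)
    dis_axes <- cbind(runif(n_dis, 16, 24), runif(n_dis, 16, 24))

    px <- array(0, c(spec$height, spec$width, 3))
    for (ch in 1:3) px[, , ch] <- spec$background_color[ch]
    ctrs <- t(vapply(spec$tissue_blobs, function(b) b$center, c(0, 0)))
    for (k in seq_along(spec$tissue_blobs)) {
      b <- spec$tissue_blobs[[k]]
      px <- paint_rgb_discs(px, ctrs[k, , drop = FALSE], b$radius, b$color)
    }
    if (n_dis > 0L) px <- paint_ellipses(px, dis_centers, dis_axes,
                                         spec$distractor_color)
    px <- paint_rgb_discs(px, centers, r_lymph, spec$lymph_color)
    if (spec$noise_sd > 0) {
      px <- px + array(rnorm(length(px), sd = spec$noise_sd), dim(px))
    }
    px <- pmin(pmax(round(px), 0), 255)

    labs <- cpp_label_components(tissue_mask, 8L)
    bbox <- if (max(labs) == 0L) NULL else {
      tab <- tabulate(labs[labs > 0])
      best <- which.max(tab) # ties: smallest label = first in row-major scan
      idx <- which(labs == best, arr.ind = TRUE)
      til_box(min(idx[, 1]) - 1L, min(idx[, 2]) - 1L,
              max(idx[, 1]), max(idx[, 2]))
    }
    list(
      slide = raster_slide(px),
      truth = list(tissue_mask = tissue_mask, tissue_bbox = bbox,
                   lymph_centers = centers)
    )
  })
}

#' Write a generated slide and its ground truth to disk
#'
#' The slide goes to `<prefix>.ppm`, lymphocyte centers to
#' `<prefix>_centers.csv` (`row,col`, 0-based), and bounding box + spec echo
#' to `<prefix>_truth.json`.
#'
#' @param gen result of [generate_slide()].
#' @param prefix output path prefix.
#' @return the three paths, invisibly.
#' @export
write_slide_truth <- function(gen, prefix) {
  p1 <- paste0(prefix, ".ppm")
  p2 <- paste0(prefix, "_centers.csv")
  p3 <- paste0(prefix, "_truth.json")
  write_slide(gen$slide, p1)
  df <- as.data.frame(gen$truth$lymph_centers)
  names(df) <- c("row", "col")
  write_csv_meta(df, p2)
  jsonlite::write_json(list(tissue_bbox = as.integer(gen$truth$tissue_bbox)),
                       p3, auto_unbox = TRUE)
  invisible(c(p1, p2, p3))
}
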