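# Spatial TIL features: TIL patches become data points on the patch grid,
# affinity propagation finds local TIL clusters, and the 42 cluster-validity
# indices (plus the TIL score itself) form the slide's feature vector.

#' Select TIL patches as spatial data points
#'
#' A valid patch counts as a "TIL patch" when its lymphocyte fraction
#' `L_i / T_i` is at least `min_fraction` (default 0.1; the selection
#' threshold is recorded in the result).
#'
#' @param map a `til_map`.
#' @param min_fraction minimum lymphocyte fraction (default 0.1).
#' @return object of class `til_points`: `points` matrix of
#'   `(grid_row, grid_col)` plus the threshold used. May be empty.
#' @export
select_til_patches <- function(map, min_fraction = 0.1) {
  ent <- map$entries
  keep <- ent$valid & !is.na(ent$Ti) & ent$Ti > 0 &
    (ent$Li / ent$Ti) >= min_fraction
  pts <- as.matrix(ent[keep, c("grid_row", "grid_col")])
  rownames(pts) <- NULL
  structure(list(points = pts, min_fraction = min_fraction),
            class = "til_points")
}

#' @method print til_points
#' @export
print.til_points <- function(x, ...) {
  cat(sprintf("<til_points: %d TIL patches (threshold %.3g)>\n",
              nrow(x$points), x$min_fraction))
  invisible(x)
}

#' Compute the spatial feature vector of a TIL map
#'
#' Pipeline: TIL-patch selection, affinity propagation on the patch-grid
#' points, then every registry index. The TIL score is always present;
#' spatial indices are NA when fewer than 2 points or a single cluster make
#' them undefined.
#'
#' @param map a `til_map`.
#' @param min_fraction TIL-patch selection threshold.
#' @param preference,damping,max_iter,conv_iter affinity propagation
#'   parameters (see [affinity_propagation()]).
#' @return object of class `til_features`: named numeric `values`
#'   (`til_score` + 42 indices), the `clustering`, the `points`, and the
#'   parameters used.
#' @export
compute_feature_vector <- function(map, min_fraction = 0.1,
                                   preference = "median", damping = 0.9,
                                   max_iter = 1000L, conv_iter = 100L) {
  score <- tryCatch(til_score(map), error = function(e) 0)
  sel <- select_til_patches(map, min_fraction)
  n <- nrow(sel$points)
  vals <- setNames(rep(NA_real_, length(validity_index_names())),
                   validity_index_names())
  clustering <- NULL
  if (n >= 2L) {
    clustering <- affinity_propagation(sel$points, preference = preference,
                                       damping = damping,
                                       max_iter = max_iter,
                                       conv_iter = conv_iter)
    vals <- compute_all_indices(sel$points, clustering)
  }
  structure(list(values = c(til_score = score, vals),
                 points = sel, clustering = clustering,
                 params = list(min_fraction = min_fraction,
                               preference = preference, damping = damping,
                               max_iter = max_iter, conv_iter = conv_iter)),
            class = "til_features")
}

#' @method print til_features
#' @export
print.til_features <- function(x, ...) {
  nmiss <- sum(is.na(x$values))
  cat(sprintf("<til_features: til_score %.4f, %d/%d indices defined>\n",
              x$values[["til_score"]], length(x$values) - 1 - nmiss,
              length(x$values) - 1))
  invisible(x)
}

#' Write / read a feature vector as a one-row CSV
#'
#' Missing (undefined) indices are written as empty fields and restored as
#' NA - never zero-filled.
#'
#' @param fv a `til_features` (or named numeric vector).
#' @param path CSV path.
#' @param slide_id identifier written in the first column.
#' @param seed recorded in the metadata header.
#' @return `path` / named numeric vector.
#' @export
write_feature_vector <- function(fv, path, slide_id = "slide", seed = NULL) {
  vals <- if (inherits(fv, "til_features")) fv$values else fv
  df <- cbind(data.frame(slide_id = slide_id),
              as.data.frame(as.list(vals), check.names = FALSE))
  write_csv_meta(df, path, seed = seed)
}

#' @rdname write_feature_vector
#' @export
read_feature_vector <- function(path) {
  df <- read_csv_meta(path)
  vals <- as.numeric(df[1, -1])
  names(vals) <- names(df)[-1]
  vals
}

#' Write cluster assignments as CSV
#' @param fv a `til_features` with a clustering.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_clusters <- function(fv, path) {
  stopifnot(inherits(fv, "til_features"))
  if (is.null(fv$clustering)) {
    df <- data.frame(point_row = integer(0), point_col = integer(0),
                     cluster = integer(0), exemplar = logical(0))
  } else {
    pts <- fv$points$points
    df <- data.frame(point_row = pts[, 1], point_col = pts[, 2],
                     cluster = fv$clustering$labels,
                     exemplar = seq_len(nrow(pts)) %in% fv$clustering$exemplars)
  }
  write_csv_meta(df, path)
}
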