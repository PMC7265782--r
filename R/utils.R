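#' @useDynLib tilscope, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats kmeans quantile rnorm runif rpois rexp rbinom cor sd
#'   pchisq wilcox.test median complete.cases setNames aggregate
#' @importFrom utils write.csv read.csv head modifyList
NULL

# All pixel/grid coordinates in this package are 0-based and row-major;
# rectangles are half-open [r0, r1) x [c0, c1). R arrays are 1-based, so
# array access adds 1. This convention is stated once here and used everywhere.

#' Derive a child RNG seed from a master seed and a stage tag
#'
#' Every stochastic stage of the pipeline draws its seed deterministically
#' from one top-level seed so that a single `--seed` reproduces a full run.
#' The derivation is a small multiplicative hash kept below 2^31.
#'
#' @param seed master integer seed.
#' @param tag character stage tag (e.g. `"fov"`, `"train"`).
#' @return an integer seed in `[1, 2^31 - 1]`.
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  h <- as.double(seed %% m)
  for (ch in utf8ToInt(tag)) {
    h <- (h * 69069 + ch * 2654435761) %% m
  }
  as.integer(h %% (m - 1L) + 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Half-open rectangle constructor
#'
#' @param r0,c0 top-left corner (0-based, inclusive).
#' @param r1,c1 bottom-right corner (exclusive).
#' @return named integer vector of class `til_box`.
#' @export
til_box <- function(r0, c0, r1, c1) {
  b <- as.integer(c(r0 = r0, c0 = c0, r1 = r1, c1 = c1))
  names(b) <- c("r0", "c0", "r1", "c1")
  if (b["r1"] < b["r0"] || b["c1"] < b["c0"]) {
    stop("invalid box: negative extent")
  }
  class(b) <- "til_box"
  b
}

box_area <- function(b) {
  as.double(b[["r1"]] - b[["r0"]]) * as.double(b[["c1"]] - b[["c0"]])
}

box_intersect <- function(a, b) {
  r0 <- max(a[["r0"]], b[["r0"]]); c0 <- max(a[["c0"]], b[["c0"]])
  r1 <- min(a[["r1"]], b[["r1"]]); c1 <- min(a[["c1"]], b[["c1"]])
  if (r1 <= r0 || c1 <= c0) return(NULL)
  til_box(r0, c0, r1, c1)
}

#' Intersection-over-union of two half-open boxes
#' @param a,b `til_box` objects.
#' @return numeric in `[0, 1]`.
#' @export
box_iou <- function(a, b) {
  i <- box_intersect(a, b)
  if (is.null(i)) return(0)
  ia <- box_area(i)
  ia / (box_area(a) + box_area(b) - ia)
}

#' @method print til_box
#' @export
print.til_box <- function(x, ...) {
  cat(sprintf("<box rows [%d,%d) cols [%d,%d)>\n",
              x[["r0"]], x[["r1"]], x[["c0"]], x[["c1"]]))
  invisible(x)
}

# scale a low-resolution half-open box up by an integer factor, clipped
scale_box <- function(b, factor, rows, cols) {
  til_box(
    min(b[["r0"]] * factor, rows), min(b[["c0"]] * factor, cols),
    min(b[["r1"]] * factor, rows), min(b[["c1"]] * factor, cols)
  )
}

assert_scalar_num <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi) {
    stop(sprintf("`%s` must be a single number in [%s, %s]", name, lo, hi))
  }
  invisible(x)
}

# metadata comment header written at the top of every CSV the pipeline emits
meta_header <- function(seed = NULL, extra = list()) {
  fields <- c(
    list(package = "tilscope",
         version = as.character(utils::packageVersion("tilscope"))),
    if (!is.null(seed)) list(seed = seed),
    extra
  )
  paste0("# ", names(fields), ": ", vapply(fields, as.character, ""))
}

write_csv_meta <- function(df, path, seed = NULL, extra = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta_header(seed, extra), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

read_csv_meta <- function(path) {
  read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
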