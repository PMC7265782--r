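# Affinity propagation (Frey-Dueck message passing): clusters emerge as
# exemplar points through alternating responsibility/availability updates on
# a similarity matrix; the shared "preference" on the diagonal controls how
# many exemplars survive.

#' Affinity propagation clustering
#'
#' Similarities are negative squared Euclidean distances; the preference
#' (self-similarity) defaults to the median off-diagonal similarity.
#' Messages are damped and iterated until the exemplar set is stable for
#' `conv_iter` consecutive sweeps or `max_iter` is reached (then the
#' best-so-far solution is returned with `converged = FALSE`). After
#' convergence, exemplars are refined to the cluster medoids and points
#' reassigned, as in the reference implementations.
#'
#' @param points numeric matrix (rows = points) with >= 1 row.
#' @param preference numeric scalar, or `"median"` (default).
#' @param damping message damping in `[0.5, 1)` (default 0.9).
#' @param max_iter maximum sweeps (default 1000).
#' @param conv_iter required stable sweeps to declare convergence
#'   (default 100).
#' @return object of class `ap_clustering`: `labels` (1..k, exemplars label
#'   themselves), `exemplars` (row indices), `k`, `iterations`,
#'   `converged`, `preference`, `damping`, `net_similarity`.
#' @export
affinity_propagation <- function(points, preference = "median",
                                 damping = 0.9, max_iter = 1000L,
                                 conv_iter = 100L) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 1L) stop("affinity propagation needs at least one point")
  if (damping < 0.5 || damping >= 1) stop("damping must be in [0.5, 1)")
  if (n == 1L) {
    return(structure(list(labels = 1L, exemplars = 1L, k = 1L,
                          iterations = 0L, converged = TRUE,
                          preference = 0, damping = damping,
                          net_similarity = 0),
                     class = "ap_clustering"))
  }
  D2 <- as.matrix(dist(points))^2
  if (max(D2) == 0) { # n identical points: zero dissimilarity, one cluster
    return(structure(list(labels = rep(1L, n), exemplars = 1L, k = 1L,
                          iterations = 0L, converged = TRUE,
                          preference = 0, damping = damping,
                          net_similarity = 0),
                     class = "ap_clustering"))
  }
  S <- -D2
  pref <- if (identical(preference, "median")) {
    median(S[row(S) != col(S)])
  } else {
    as.numeric(preference)
  }
  diag(S) <- pref
  # tiny deterministic jitter breaks exact symmetry ties (standard trick),
  # scaled far below distance resolution
  noise <- outer(seq_len(n), seq_len(n),
                 function(i, j) ((i * 31 + j * 17) %% 97) - 48)
  S <- S + noise * 1e-10 * (max(abs(S)) + 1)

  R <- matrix(0, n, n); A <- matrix(0, n, n)
  e_hist <- matrix(FALSE, n, conv_iter)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    # responsibilities
    AS <- A + S
    m1 <- apply(AS, 1, max)
    i1 <- max.col(AS, ties.method = "first")
    AS2 <- AS
    AS2[cbind(seq_len(n), i1)] <- -Inf
    m2 <- apply(AS2, 1, max)
    Rnew <- S - m1
    Rnew[cbind(seq_len(n), i1)] <- S[cbind(seq_len(n), i1)] - m2
    R <- damping * R + (1 - damping) * Rnew
    # availabilities
    Rp <- pmax(R, 0)
    diag(Rp) <- diag(R)
    colsum <- colSums(Rp)
    Anew <- matrix(colsum, n, n, byrow = TRUE) - Rp
    dA <- diag(Anew)
    Anew <- pmin(Anew, 0)
    diag(Anew) <- dA
    A <- damping * A + (1 - damping) * Anew

    ex <- (diag(A) + diag(R)) > 0
    e_hist[, (it - 1L) %% conv_iter + 1L] <- ex
    if (it >= conv_iter) {
      se <- rowSums(e_hist)
      if (all(se == 0L | se == conv_iter) && any(ex)) {
        converged <- TRUE
        break
      }
    }
  }
  ex_idx <- which((diag(A) + diag(R)) > 0)
  if (length(ex_idx) == 0L) ex_idx <- which.max(diag(A) + diag(R))
  labels <- apply(S[, ex_idx, drop = FALSE], 1, which.max)
  labels[ex_idx] <- seq_along(ex_idx)
  # medoid refinement within each cluster
  for (cl in seq_along(ex_idx)) {
    members <- which(labels == cl)
    if (length(members) > 1L) {
      sums <- colSums(S[members, members, drop = FALSE])
      ex_idx[cl] <- members[which.max(sums)]
    }
  }
  ex_idx <- sort(ex_idx)
  labels <- apply(S[, ex_idx, drop = FALSE], 1, which.max)
  labels[ex_idx] <- seq_along(ex_idx)
  net <- sum(S[cbind(seq_len(n), ex_idx[labels])])
  structure(list(labels = as.integer(labels), exemplars = ex_idx,
                 k = length(ex_idx), iterations = it, converged = converged,
                 preference = pref, damping = damping,
                 net_similarity = net),
            class = "ap_clustering")
}

#' @method print ap_clustering
#' @export
print.ap_clustering <- function(x, ...) {
  cat(sprintf("<ap_clustering: k = %d, %d iterations, converged = %s>\n",
              x$k, x$iterations, x$converged))
  invisible(x)
}

#' Exact exemplar search by net-similarity maximization
#'
#' Brute-force reference for tiny instances: enumerates every nonempty
#' exemplar subset and assigns each point to its best exemplar. Exponential
#' in n - intended for n <= 12.
#'
#' @param points numeric matrix of points.
#' @param preference numeric scalar or `"median"`.
#' @return `list(exemplars, labels, net_similarity)`.
#' @export
ap_brute_force <- function(points, preference = "median") {
  points <- as.matrix(points)
  n <- nrow(points)
  stopifnot(n >= 1, n <= 12)
  S <- -as.matrix(dist(points))^2
  pref <- if (identical(preference, "median")) {
    median(S[row(S) != col(S)])
  } else {
    as.numeric(preference)
  }
  diag(S) <- pref
  best <- NULL
  for (mask in seq_len(2^n - 1L)) {
    ex <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
    lab <- apply(S[, ex, drop = FALSE], 1, which.max)
    lab[ex] <- seq_along(ex) # exemplars represent themselves
    net <- sum(S[cbind(seq_len(n), ex[lab])])
    if (is.null(best) || net > best$net_similarity) {
      best <- list(exemplars = ex, labels = lab, net_similarity = net)
    }
  }
  best
}
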