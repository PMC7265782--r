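# Internal cluster-validity indices. The registry reproduces the standard
# 42-index internal set of the clustering-indices literature (Desgraupes'
# conventions): sum-of-squares ratios, scatter-matrix determinants,
# pair-concordance statistics, the generalized Dunn family, and
# density/dispersion scores. Indices that are undefined for a clustering
# (k = 1, singular scatter, zero denominators) return NA rather than a
# fabricated value.

# shared per-clustering precomputation
index_env <- function(points, labels) {
  X <- as.matrix(points)
  labels <- as.integer(factor(labels))
  n <- nrow(X); d <- ncol(X); k <- max(labels)
  sizes <- tabulate(labels, k)
  G <- colMeans(X)
  Gk <- matrix(0, k, d)
  for (c in seq_len(k)) Gk[c, ] <- colMeans(X[labels == c, , drop = FALSE])
  cent <- Gk[labels, , drop = FALSE]
  dev_w <- X - cent
  dev_t <- sweep(X, 2, G)
  WGSS_k <- vapply(seq_len(k), function(c) sum(dev_w[labels == c, ]^2), 0)
  WGSS <- sum(WGSS_k)
  TSS <- sum(dev_t^2)
  BGSS <- TSS - WGSS
  Wmat <- crossprod(dev_w)
  Tmat <- crossprod(dev_t)
  Bmat <- Tmat - Wmat
  DM <- as.matrix(dist(X))
  same <- outer(labels, labels, `==`)
  ut <- upper.tri(DM)
  dw <- DM[ut & same]
  db <- DM[ut & !same]
  cd <- as.matrix(dist(Gk)) # centroid distances
  # per-point distance to own centroid
  dcent <- sqrt(rowSums(dev_w^2))
  list(X = X, labels = labels, n = n, d = d, k = k, sizes = sizes,
       G = G, Gk = Gk, WGSS_k = WGSS_k, WGSS = WGSS, BGSS = BGSS, TSS = TSS,
       Wmat = Wmat, Tmat = Tmat, Bmat = Bmat, DM = DM, dw = dw, db = db,
       cd = cd, dcent = dcent)
}

#' Concordance counts between within- and between-cluster distances
#'
#' For every pair of (within-cluster, between-cluster) distance pairs,
#' `s_plus` counts concordant comparisons (within < between) and `s_minus`
#' discordant ones (within > between); ties count for neither. `n_w`/`n_b`
#' are the within/between pair counts. These counts underlie the Gamma,
#' G(+), and Tau indices.
#'
#' @param distances a `dist`, full distance matrix, or point matrix (rows =
#'   points; distances computed internally).
#' @param labels integer cluster labels per point.
#' @return `list(s_plus, s_minus, n_w, n_b)`; errors if fewer than two
#'   clusters.
#' @export
concordance_counts <- function(distances, labels) {
  labels <- as.integer(factor(labels))
  if (max(labels) < 2) stop("concordance counts need at least two clusters")
  DM <- if (inherits(distances, "dist")) {
    as.matrix(distances)
  } else if (is.matrix(distances) && nrow(distances) == ncol(distances) &&
             isTRUE(all.equal(unname(distances), unname(t(distances))))) {
    distances
  } else {
    as.matrix(dist(distances))
  }
  stopifnot(nrow(DM) == length(labels))
  ut <- upper.tri(DM)
  same <- outer(labels, labels, `==`)
  dw <- DM[ut & same]
  db <- sort(DM[ut & !same])
  n_w <- length(dw); n_b <- length(db)
  le <- findInterval(dw, db)                   # b <= w
  lt <- findInterval(dw, db, left.open = TRUE) # b <  w
  s_plus <- sum(n_b - le)  # within strictly smaller than between
  s_minus <- sum(lt)       # within strictly larger
  list(s_plus = s_plus, s_minus = s_minus, n_w = n_w, n_b = n_b)
}

# generalized Dunn numerators (between-cluster separation, 5 definitions)
gdi_delta <- function(e, u) {
  k <- e$k
  out <- matrix(Inf, k, k)
  for (a in seq_len(k - 1)) for (b in (a + 1):k) {
    ia <- e$labels == a; ib <- e$labels == b
    v <- switch(u,
      `1` = min(e$DM[ia, ib]),
      `2` = max(e$DM[ia, ib]),
      `3` = mean(e$DM[ia, ib]),
      `4` = e$cd[a, b],
      `5` = (sum(e$dcent[ia]) + sum(e$dcent[ib])) / (e$sizes[a] + e$sizes[b])
    )
    out[a, b] <- out[b, a] <- v
  }
  min(out[upper.tri(out)])
}

# generalized Dunn denominators (within-cluster spread, 3 definitions)
gdi_Delta <- function(e, v) {
  vals <- vapply(seq_len(e$k), function(c) {
    ic <- e$labels == c
    nc <- e$sizes[c]
    switch(v,
      `1` = if (nc > 1) max(e$DM[ic, ic]) else 0,
      `2` = if (nc > 1) sum(e$DM[ic, ic]) / (nc * (nc - 1)) else 0,
      `3` = 2 * sum(e$dcent[ic]) / nc
    )
  }, 0)
  max(vals)
}

gdi_index <- function(e, u, v) {
  if (e$k < 2) return(NA_real_)
  den <- gdi_Delta(e, v)
  if (den == 0) return(NA_real_)
  gdi_delta(e, u) / den
}

safe_det <- function(m) {
  d <- det(m)
  if (!is.finite(d)) NA_real_ else d
}

index_fns <- list(
  ball_hall = function(e) mean(e$WGSS_k / e$sizes),
  banfeld_raftery = function(e) {
    if (any(e$WGSS_k <= 0)) return(NA_real_)
    sum(e$sizes * log(e$WGSS_k / e$sizes))
  },
  c_index = function(e) {
    if (e$k < 2 || length(e$dw) == 0) return(NA_real_)
    nw <- length(e$dw)
    alld <- sort(c(e$dw, e$db))
    smin <- sum(alld[seq_len(nw)])
    smax <- sum(alld[seq(length(alld) - nw + 1, length(alld))])
    if (smax == smin) return(NA_real_)
    (sum(e$dw) - smin) / (smax - smin)
  },
  calinski_harabasz = function(e) {
    if (e$k < 2 || e$WGSS == 0 || e$n == e$k) return(NA_real_)
    (e$BGSS / (e$k - 1)) / (e$WGSS / (e$n - e$k))
  },
  davies_bouldin = function(e) {
    if (e$k < 2) return(NA_real_)
    delta <- vapply(seq_len(e$k),
                    function(c) mean(e$dcent[e$labels == c]), 0)
    mean(vapply(seq_len(e$k), function(a) {
      max(vapply(setdiff(seq_len(e$k), a),
                 function(b) (delta[a] + delta[b]) / e$cd[a, b], 0))
    }, 0))
  },
  det_ratio = function(e) {
    dw <- safe_det(e$Wmat)
    if (is.na(dw) || dw <= 0) return(NA_real_)
    safe_det(e$Tmat) / dw
  },
  dunn = function(e) gdi_index(e, 1, 1),
  gamma = function(e) {
    if (e$k < 2) return(NA_real_)
    cc <- concordance_counts(e$DM, e$labels)
    den <- cc$s_plus + cc$s_minus
    if (den == 0) return(0)
    (cc$s_plus - cc$s_minus) / den
  },
  g_plus = function(e) {
    if (e$k < 2) return(NA_real_)
    cc <- concordance_counts(e$DM, e$labels)
    nt <- e$n * (e$n - 1) / 2
    2 * cc$s_minus / (nt * (nt - 1))
  },
  ksq_detw = function(e) e$k^2 * safe_det(e$Wmat),
  log_det_ratio = function(e) {
    r <- index_fns$det_ratio(e)
    if (is.na(r) || r <= 0) return(NA_real_)
    e$n * log(r)
  },
  log_ss_ratio = function(e) {
    if (e$k < 2 || e$WGSS == 0 || e$BGSS <= 0) return(NA_real_)
    log(e$BGSS / e$WGSS)
  },
  mcclain_rao = function(e) {
    if (e$k < 2 || length(e$dw) == 0 || mean(e$db) == 0) return(NA_real_)
    mean(e$dw) / mean(e$db)
  },
  pbm = function(e) {
    if (e$k < 2) return(NA_real_)
    et <- sum(sqrt(rowSums(sweep(e$X, 2, e$G)^2)))
    ew <- sum(e$dcent)
    if (ew == 0) return(NA_real_)
    db <- max(e$cd[upper.tri(e$cd)])
    ((1 / e$k) * (et / ew) * db)^2
  },
  point_biserial = function(e) {
    if (e$k < 2 || length(e$dw) == 0) return(NA_real_)
    nw <- length(e$dw); nb <- length(e$db); nt <- nw + nb
    (mean(e$dw) - mean(e$db)) * sqrt(nw * nb) / nt
  },
  ratkowsky_lance = function(e) {
    if (e$k < 2) return(NA_real_)
    bg <- colSums(e$sizes * sweep(e$Gk, 2, e$G)^2)
    ts <- colSums(sweep(e$X, 2, e$G)^2)
    if (any(ts == 0)) return(NA_real_)
    sqrt(mean(bg / ts)) / sqrt(e$k)
  },
  ray_turi = function(e) {
    if (e$k < 2) return(NA_real_)
    md <- min(e$cd[upper.tri(e$cd)])^2
    if (md == 0) return(NA_real_)
    (e$WGSS / e$n) / md
  },
  scott_symons = function(e) {
    dets <- vapply(seq_len(e$k), function(c) {
      ic <- e$labels == c
      dv <- e$X[ic, , drop = FALSE] -
        matrix(e$Gk[c, ], sum(ic), e$d, byrow = TRUE)
      safe_det(crossprod(dv) / e$sizes[c])
    }, 0)
    if (any(is.na(dets)) || any(dets <= 0)) return(NA_real_)
    sum(e$sizes * log(dets))
  },
  sd_scat = function(e) {
    vt <- apply(e$X, 2, function(col) mean((col - mean(col))^2))
    nvt <- sqrt(sum(vt^2))
    if (nvt == 0) return(NA_real_)
    nv <- vapply(seq_len(e$k), function(c) {
      xc <- e$X[e$labels == c, , drop = FALSE]
      vc <- apply(xc, 2, function(col) mean((col - mean(col))^2))
      sqrt(sum(vc^2))
    }, 0)
    mean(nv) / nvt
  },
  sd_dis = function(e) {
    if (e$k < 2) return(NA_real_)
    offd <- e$cd[upper.tri(e$cd)]
    dmax <- max(offd); dmin <- min(offd)
    if (dmin == 0) return(NA_real_)
    s <- sum(vapply(seq_len(e$k),
                    function(a) 1 / sum(e$cd[a, -a]), 0))
    (dmax / dmin) * s
  },
  s_dbw = function(e) {
    if (e$k < 2) return(NA_real_)
    scat <- index_fns$sd_scat(e)
    if (is.na(scat)) return(NA_real_)
    nv <- vapply(seq_len(e$k), function(c) {
      xc <- e$X[e$labels == c, , drop = FALSE]
      vc <- apply(xc, 2, function(col) mean((col - mean(col))^2))
      sqrt(sum(vc^2))
    }, 0)
    sigma <- sqrt(sum(nv)) / e$k
    dens <- function(u, members) {
      if (sigma == 0) return(sum(colSums((t(e$X[members, , drop = FALSE]) - u)^2) == 0))
      sum(sqrt(colSums((t(e$X[members, , drop = FALSE]) - u)^2)) <= sigma)
    }
    tot <- 0
    for (a in seq_len(e$k - 1)) for (b in (a + 1):e$k) {
      members <- which(e$labels %in% c(a, b))
      da <- dens(e$Gk[a, ], members)
      db <- dens(e$Gk[b, ], members)
      dh <- dens((e$Gk[a, ] + e$Gk[b, ]) / 2, members)
      m <- max(da, db)
      tot <- tot + if (m > 0) dh / m else 0
    }
    scat + 2 * tot / (e$k * (e$k - 1))
  },
  silhouette = function(e) {
    if (e$k < 2) return(NA_real_)
    s <- vapply(seq_len(e$n), function(i) {
      own <- e$labels[i]
      if (e$sizes[own] == 1) return(0)
      a <- sum(e$DM[i, e$labels == own]) / (e$sizes[own] - 1)
      b <- min(vapply(setdiff(seq_len(e$k), own),
                      function(c) mean(e$DM[i, e$labels == c]), 0))
      (b - a) / max(a, b)
    }, 0)
    mean(s)
  },
  tau = function(e) {
    if (e$k < 2) return(NA_real_)
    cc <- concordance_counts(e$DM, e$labels)
    nt <- e$n * (e$n - 1) / 2
    den <- sqrt(as.double(cc$n_b) * cc$n_w * (nt * (nt - 1) / 2))
    if (den == 0) return(NA_real_)
    (cc$s_plus - cc$s_minus) / den
  },
  trace_w = function(e) e$WGSS,
  trace_wib = function(e) {
    if (e$k < 2) return(NA_real_)
    wi <- tryCatch(solve(e$Wmat), error = function(err) NULL)
    if (is.null(wi)) return(NA_real_)
    sum(diag(wi %*% e$Bmat))
  },
  wemmert_gancarski = function(e) {
    if (e$k < 2) return(NA_real_)
    dG <- vapply(seq_len(e$k), function(c) {
      sqrt(rowSums(sweep(e$X, 2, e$Gk[c, ])^2))
    }, numeric(e$n)) # n x k distances to each centroid
    dG <- matrix(dG, nrow = e$n)
    tot <- 0
    for (c in seq_len(e$k)) {
      ic <- which(e$labels == c)
      own <- dG[ic, c]
      oth <- apply(dG[ic, -c, drop = FALSE], 1, min)
      if (any(oth == 0)) return(NA_real_)
      tot <- tot + max(0, e$sizes[c] - sum(own / oth))
    }
    tot / e$n
  },
  xie_beni = function(e) {
    if (e$k < 2) return(NA_real_)
    md <- gdi_delta(e, 1)^2
    if (md == 0) return(NA_real_)
    (e$WGSS / e$n) / md
  }
)

# add the 15 generalized Dunn variants
for (.u in 1:5) for (.v in 1:3) {
  local({
    u <- .u; v <- .v
    index_fns[[sprintf("gdi%d%d", u, v)]] <<- function(e) gdi_index(e, u, v)
  })
}
rm(.u, .v)

# canonical registry order: alphabetical with the gdi block in place
.index_registry <- c(
  "ball_hall", "banfeld_raftery", "c_index", "calinski_harabasz",
  "davies_bouldin", "det_ratio", "dunn", "gamma", "g_plus",
  sprintf("gdi%d%d", rep(1:5, each = 3), rep(1:3, 5)),
  "ksq_detw", "log_det_ratio", "log_ss_ratio", "mcclain_rao", "pbm",
  "point_biserial", "ratkowsky_lance", "ray_turi", "scott_symons",
  "sd_scat", "sd_dis", "s_dbw", "silhouette", "tau", "trace_w",
  "trace_wib", "wemmert_gancarski", "xie_beni"
)

#' Names of the 42 cluster-validity indices
#' @return character vector of registry names, in canonical order.
#' @export
validity_index_names <- function() .index_registry

#' Compute one internal cluster-validity index
#'
#' @param name registry name (see [validity_index_names()]).
#' @param points numeric matrix of points.
#' @param clustering an `ap_clustering`, or an integer label vector.
#' @return numeric value, `NA` when the index is undefined for this
#'   clustering (e.g. a single cluster, or a zero-scatter cluster for
#'   log-based indices).
#' @export
compute_validity_index <- function(name, points, clustering) {
  if (!name %in% .index_registry) stop("unknown validity index: ", name)
  labels <- if (inherits(clustering, "ap_clustering")) {
    clustering$labels
  } else {
    clustering
  }
  e <- index_env(points, labels)
  index_fns[[name]](e)
}

#' Compute all registry indices at once
#' @inheritParams compute_validity_index
#' @return named numeric vector over the full registry.
#' @export
compute_all_indices <- function(points, clustering) {
  labels <- if (inherits(clustering, "ap_clustering")) {
    clustering$labels
  } else {
    clustering
  }
  e <- index_env(points, labels)
  vapply(.index_registry, function(nm) index_fns[[nm]](e), 0)
}
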