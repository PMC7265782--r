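# Validity indices against independent oracles: exhaustive pair-of-pairs
# concordance loops, direct formula evaluation on hand cases, and geometric
# invariances.

test_that("concordance_counts equals the O(n^4) brute-force oracle", {
  # the 4-point line case, worked by hand: W = {1, 1}, B = {9, 10, 10, 11}
  X <- cbind(c(0, 1, 10, 11), 0)
  cc <- concordance_counts(X, c(1, 1, 2, 2))
  expect_equal(unname(unlist(cc)), c(8, 0, 2, 4))

  for (s in 1:8) {
    set.seed(s)
    n <- sample(6:14, 1)
    k <- sample(2:3, 1)
    X <- matrix(runif(2 * n, 0, 5), n)
    lab <- sample(seq_len(k), n, replace = TRUE)
    if (length(unique(lab)) < 2) lab[1:2] <- 1:2
    a <- concordance_counts(X, lab)
    b <- bf_concordance(X, lab)
    expect_equal(as.numeric(unlist(a)), as.numeric(unlist(b)))
  }
  expect_error(concordance_counts(cbind(1:4, 0), rep(1, 4)), "two clusters")
})

test_that("concordance edge cases: perfect separation and full ties", {
  # two tight clusters far apart: no discordance
  X <- rbind(c(0, 0), c(0, 1), c(100, 0), c(100, 1))
  lab <- c(1, 1, 2, 2)
  cc <- concordance_counts(X, lab)
  expect_equal(cc$s_minus, 0)
  expect_equal(compute_validity_index("gamma", X, lab), 1)
  expect_equal(compute_validity_index("g_plus", X, lab), 0)

  # all within-distances equal all between-distances (regular tetrahedron):
  # everything ties
  tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  cc2 <- concordance_counts(tet, c(1, 1, 2, 2))
  expect_equal(cc2$s_plus + cc2$s_minus, 0)
  expect_equal(compute_validity_index("gamma", tet, c(1, 1, 2, 2)), 0)
})

test_that("pair-counting indices match direct pair-list formulas", {
  for (s in 1:6) {
    set.seed(100 + s)
    n <- sample(8:30, 1)
    X <- matrix(rnorm(2 * n), n)
    lab <- sample(1:3, n, replace = TRUE)
    if (length(unique(lab)) < 2) lab[1:2] <- 1:2
    D <- as.matrix(dist(X))
    ut <- upper.tri(D)
    same <- outer(lab, lab, `==`)
    dw <- D[ut & same]; db <- D[ut & !same]
    nw <- length(dw); nb <- length(db); nt <- nw + nb
    if (nw == 0) next
    cc <- bf_concordance(X, lab)

    alld <- sort(c(dw, db))
    c_or <- (sum(dw) - sum(alld[1:nw])) /
      (sum(alld[(nt - nw + 1):nt]) - sum(alld[1:nw]))
    expect_equal(compute_validity_index("c_index", X, lab), c_or)

    expect_equal(compute_validity_index("mcclain_rao", X, lab),
                 mean(dw) / mean(db))
    expect_equal(compute_validity_index("point_biserial", X, lab),
                 (mean(dw) - mean(db)) * sqrt(nw * nb) / nt)
    expect_equal(compute_validity_index("gamma", X, lab),
                 (cc$s_plus - cc$s_minus) / (cc$s_plus + cc$s_minus))
    expect_equal(compute_validity_index("g_plus", X, lab),
                 2 * cc$s_minus / (nt * (nt - 1)))
    expect_equal(compute_validity_index("tau", X, lab),
                 (cc$s_plus - cc$s_minus) /
                   sqrt(nb * nw * (nt * (nt - 1) / 2)))
  }
})

test_that("scatter-based indices match direct formula oracles on a hand case", {
  X <- rbind(c(0, 0), c(2, 0), c(1, 1), c(10, 10), c(12, 10), c(11, 11))
  lab <- c(1, 1, 1, 2, 2, 2)
  wgss_k <- function(xs) sum(sweep(xs, 2, colMeans(xs))^2)
  w1 <- wgss_k(X[1:3, ]); w2 <- wgss_k(X[4:6, ])
  W <- w1 + w2
  Ttot <- wgss_k(X)
  B <- Ttot - W
  n <- 6; k <- 2

  expect_equal(compute_validity_index("ball_hall", X, lab), mean(c(w1 / 3, w2 / 3)))
  expect_equal(compute_validity_index("banfeld_raftery", X, lab),
               3 * log(w1 / 3) + 3 * log(w2 / 3))
  expect_equal(compute_validity_index("calinski_harabasz", X, lab),
               (B / (k - 1)) / (W / (n - k)))
  expect_equal(compute_validity_index("trace_w", X, lab), W)
  expect_equal(compute_validity_index("log_ss_ratio", X, lab), log(B / W))

  D <- as.matrix(dist(X))
  dunn_or <- min(D[1:3, 4:6]) / max(D[1:3, 1:3], D[4:6, 4:6])
  expect_equal(compute_validity_index("dunn", X, lab), dunn_or)
  expect_equal(compute_validity_index("gdi11", X, lab), dunn_or)

  # davies_bouldin via its definition
  G1 <- colMeans(X[1:3, ]); G2 <- colMeans(X[4:6, ])
  d1 <- mean(sqrt(rowSums(sweep(X[1:3, ], 2, G1)^2)))
  d2 <- mean(sqrt(rowSums(sweep(X[4:6, ], 2, G2)^2)))
  dbi <- mean(rep((d1 + d2) / sqrt(sum((G1 - G2)^2)), 2))
  expect_equal(compute_validity_index("davies_bouldin", X, lab), dbi)

  # xie_beni = (WGSS/n) / min between-point distance squared
  expect_equal(compute_validity_index("xie_beni", X, lab),
               (W / n) / min(D[1:3, 4:6])^2)

  # silhouette via the standard per-point formula
  sil <- mean(vapply(1:6, function(i) {
    own <- if (i <= 3) 1:3 else 4:6
    oth <- setdiff(1:6, own)
    a <- mean(D[i, setdiff(own, i)])
    b <- mean(D[i, oth])
    (b - a) / max(a, b)
  }, 0))
  expect_equal(compute_validity_index("silhouette", X, lab), sil)
})

test_that("undefined indices report missing, not fabricated values", {
  X <- matrix(rnorm(20), 10)
  expect_true(is.na(compute_validity_index("gamma", X, rep(1, 10))))
  expect_true(is.na(compute_validity_index("silhouette", X, rep(1, 10))))
  # a zero-scatter cluster breaks the log in banfeld_raftery
  X2 <- rbind(matrix(1, 3, 2), matrix(rnorm(10, 5), 5))
  expect_true(is.na(compute_validity_index("banfeld_raftery", X2,
                                           rep(1:2, c(3, 5)))))
  expect_error(compute_validity_index("bogus", X, rep(1:2, 5)), "unknown")
})

test_that("registry has 42 indices incl. the six named headline features", {
  nm <- validity_index_names()
  expect_length(nm, 42L)
  expect_true(all(c("banfeld_raftery", "g_plus", "gdi12", "pbm", "tau",
                    "gamma") %in% nm))
  expect_false(anyDuplicated(nm) > 0)
})

test_that("distance-based indices are translation and rotation invariant", {
  set.seed(19)
  X <- matrix(rnorm(40), 20)
  lab <- rep(1:2, 10)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  Xt <- sweep(X %*% R, 2, c(5, -3), `+`)
  v1 <- compute_all_indices(X, lab)
  v2 <- compute_all_indices(Xt, lab)
  # ratkowsky_lance, sd_scat and s_dbw are defined on per-coordinate
  # variances and are only translation invariant, not rotation invariant
  coord_based <- c("ratkowsky_lance", "sd_scat", "s_dbw")
  keep <- setdiff(validity_index_names(), coord_based)
  expect_equal(v1[keep], v2[keep], tolerance = 1e-8)
  v3 <- compute_all_indices(sweep(X, 2, c(7, 2), `+`), lab)
  expect_equal(v1, v3, tolerance = 1e-8)
})
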