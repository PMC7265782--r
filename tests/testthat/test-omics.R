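test_that("assign_subtype follows the marker rules", {
  mk <- data.frame(er = c("+", "-", "-", "?"),
                   pr = c("+", "-", "+", "-"),
                   her2 = c("-", "-", "+", "-"))
  s <- suppressMessages(assign_subtype(mk))
  expect_equal(s$er_positive, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(s$er_negative, c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(s$triple_negative, c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(attr(s, "excluded"), 4L)
  # triple negatives leave the ER-negative group in disjoint mode
  s2 <- suppressMessages(assign_subtype(mk, disjoint = TRUE))
  expect_equal(s2$er_negative, c(FALSE, FALSE, TRUE, FALSE))
})

test_that("spearman_screen: exact rho, sign retention, tie-broken ordering", {
  set.seed(2)
  f <- rnorm(30)
  expr <- rbind(same = f, anti = -f, noise = rnorm(30))
  colnames(expr) <- paste0("P", 1:30)
  out <- spearman_screen(setNames(f, colnames(expr)), expr, threshold = 0.3)
  expect_equal(out$rho[out$gene == "same"], 1)
  expect_equal(out$rho[out$gene == "anti"], -1)
  expect_equal(out$gene[1:2], c("anti", "same")) # |rho| tie -> alphabetical
  # exact rank-based rho equals cor(method = "spearman"), with ties
  x <- c(1, 2, 2, 3, 5, 5, 5, 8)
  y <- c(2, 1, 4, 4, 6, 7, 7, 9)
  expect_equal(tilscope:::spearman_rho(x, y),
               cor(x, y, method = "spearman"))
  expect_warning(spearman_screen(rep(1, 30), expr), "constant")
})

test_that("mutation_test filters, computes exact tails, and skips degenerates", {
  set.seed(3)
  til <- c(rnorm(10, 10), rnorm(10)) # first 10 far larger
  names(til) <- paste0("P", 1:20)
  mut <- rbind(
    g_extreme = rep(c(1, 0), each = 10),
    g_rare = c(rep(1, 9), rep(0, 11)),
    g_all = rep(1, 20)
  )
  colnames(mut) <- names(til)
  res <- suppressMessages(mutation_test(til, mut, min_mutated = 10))
  expect_false("g_rare" %in% res$gene)   # 9 carriers < 10
  expect_false("g_all" %in% res$gene)    # mutated in everyone
  expect_equal(attr(res, "skipped"), "g_all")
  # all mutated values above all wild-type: two-sided exact p = 2/C(20,10)
  expect_equal(res$p[res$gene == "g_extreme"], 2 / choose(20, 10))
  expect_error(mutation_test(til, mut, min_mutated = 0), "min_mutated")
})

test_that("mutation_test p-values are uniform under permuted labels", {
  set.seed(4)
  til <- rnorm(60)
  names(til) <- paste0("P", 1:60)
  ps <- vapply(1:300, function(i) {
    mut <- matrix(0, 1, 60, dimnames = list("g", names(til)))
    mut[1, sample(60, 15)] <- 1
    mutation_test(til, mut, min_mutated = 10)$p
  }, 0)
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("logrank_test: identical groups, hand case, and the survdiff oracle", {
  t1 <- c(3, 5, 9, 12); e1 <- c(1, 0, 1, 1)
  r <- logrank_test(t1, e1, t1, e1)
  expect_equal(r$chisq, 0)
  expect_equal(r$p, 1)

  # 4-patient hand case: A = {1, 2}, B = {3, 4}, all events
  # t=1: O=1 E=2/4 V=(1*2*2*3)/(16*3)=1/4 ; t=2: O=1 E=1/3 V=(1*1*2*2)/(9*2)=2/9
  # t=3: O=0 E=0   V=0 (n=2, both B)      ; t=4: last subject, V=0
  O <- 2; E <- 2 / 4 + 1 / 3; V <- 1 / 4 + 2 / 9
  r2 <- logrank_test(c(1, 2), c(1, 1), c(3, 4), c(1, 1))
  expect_equal(r2$chisq, (O - E)^2 / V)

  # the survival-package oracle on random censored instances
  for (s in 1:12) {
    set.seed(s)
    nA <- sample(3:20, 1); nB <- sample(3:20, 1)
    tA <- round(rexp(nA, 0.1), 1) + 0.1; tB <- round(rexp(nB, 0.15), 1) + 0.1
    eA <- rbinom(nA, 1, 0.7); eB <- rbinom(nB, 1, 0.7)
    if (sum(eA) + sum(eB) == 0) next
    mine <- logrank_test(tA, eA, tB, eB)
    sd <- survival::survdiff(
      survival::Surv(c(tA, tB), c(eA, eB)) ~ rep(1:2, c(nA, nB)))
    expect_equal(mine$chisq, sd$chisq, tolerance = 1e-10)
  }

  expect_error(logrank_test(numeric(0), numeric(0), 1, 1), "nonempty")
  r3 <- logrank_test(c(1, 2), c(0, 0), c(3, 4), c(0, 0))
  expect_true(r3$no_events)
  expect_true(is.na(r3$p))
})

test_that("cutoff scan: 61 rows, reported minimum, small-n deduplication", {
  set.seed(6)
  x <- rnorm(120); tm <- rexp(120); ev <- rbinom(120, 1, 0.8)
  sc <- univariate_cutoff_scan(x, tm, ev)
  expect_equal(nrow(sc$scan), 61L)
  expect_equal(sc$scan$percentile, 20:80)
  ok <- !sc$scan$duplicate & !is.na(sc$scan$p)
  expect_equal(sc$best$p, min(sc$scan$p[ok]))

  # n = 10: many percentiles give the same split; duplicates flagged
  x10 <- rnorm(10); t10 <- rexp(10); e10 <- rep(1, 10)
  sc10 <- univariate_cutoff_scan(x10, t10, e10)
  expect_equal(nrow(sc10$scan), 61L)
  expect_lte(sc10$n_distinct, 10L)
  expect_error(univariate_cutoff_scan(rep(1, 50), tm[1:50], ev[1:50]),
               "constant")
})

test_that("cutoff scan recovers a planted 40th-percentile threshold", {
  hits <- vapply(1:3, function(s) {
    co <- generate_cohort(cohort_spec(n_patients = 200, n_genes = 0,
                                      n_correlated_genes = 0,
                                      surv_model = "threshold",
                                      threshold_percentile = 40,
                                      surv_feature_effect = 3,
                                      censoring_rate = 0.1, seed = 600 + s))
    sc <- univariate_cutoff_scan(co$clinical$til_score, co$clinical$time,
                                 co$clinical$event)
    abs(sc$best$percentile - 40) <= 5
  }, TRUE)
  expect_gte(sum(hits), 2L)
})

test_that("K-means risk groups recover planted blobs and stay null on noise", {
  set.seed(7)
  n <- 120
  blob <- rep(c(0, 6), each = n / 2)
  X <- cbind(blob + rnorm(n, sd = 0.5), rnorm(n))
  tm <- rexp(n, ifelse(blob > 0, 0.3, 0.05))
  mg <- multivariate_risk_groups(X, tm, rep(1, n), seed = 7)
  expect_gte(adjusted_rand(mg$cluster, blob > 0), 0.9)
  expect_lt(mg$p, 0.05)

  # pure-noise features with identical hazards: median p over seeds > 0.05
  ps <- vapply(1:5, function(s) {
    set.seed(s)
    Xn <- matrix(rnorm(2 * n), n)
    tn <- rexp(n, 0.1)
    multivariate_risk_groups(Xn, tn, rep(1, n), seed = s)$p
  }, 0)
  expect_gt(median(ps), 0.05)

  # duplicating every patient preserves the clustering structure
  mg2 <- multivariate_risk_groups(rbind(X, X), c(tm, tm), rep(1, 2 * n),
                                  seed = 7)
  expect_gte(adjusted_rand(mg2$cluster, rep(blob > 0, 2)), 0.9)
})

test_that("lasso_cox_select finds the planted feature and handles collinearity", {
  co <- generate_cohort(cohort_spec(n_patients = 300, n_genes = 0,
                                    n_correlated_genes = 0,
                                    surv_feature = "feat_1",
                                    surv_feature_effect = 3,
                                    censoring_rate = 0.2, seed = 71))
  d <- co$clinical
  X <- as.matrix(d[, grep("^feat_", names(d))])
  sel <- lasso_cox_select(X, d$time, d$event, seed = 71)
  expect_true("feat_1" %in% sel$feature)
  expect_gt(sel$coefficient[sel$feature == "feat_1"], 0)

  # duplicated column: at most one of the pair enters
  X2 <- cbind(X, feat_dup = X[, "feat_1"])
  sel2 <- lasso_cox_select(X2, d$time, d$event, seed = 71)
  expect_lte(sum(sel2$feature %in% c("feat_1", "feat_dup")), 1L)

  expect_error(lasso_cox_select(X, d$time, rep(0, nrow(d))), "no events")
})
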