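# Association of TIL features with omics and outcome: subtype assignment
# from receptor markers, Spearman screening against expression, Wilcoxon
# rank-sum tests against mutation status, the log-rank test, a
# percentile-scan univariate stratification, K-means risk groups, and
# Lasso-Cox feature selection.

#' Assign breast-cancer subtype labels from receptor markers
#'
#' ER+ patients form the ER-positive group; ER- patients the ER-negative
#' group; patients negative for all of ER/PR/HER2 are additionally
#' triple-negative (membership in both the ER-negative and triple-negative
#' analyses, unless `disjoint = TRUE` removes them from ER-negative).
#' Patients with unknown ER status are excluded (NA subtype) with a log
#' attribute.
#'
#' @param markers data frame with `er`, `pr`, `her2` columns coded
#'   `"+"`/`"-"` (anything else = unknown).
#' @param disjoint make ER-negative and triple-negative disjoint.
#' @return data frame `subtype` (factor: ER-positive / ER-negative /
#'   triple-negative membership flags as logical columns `er_positive`,
#'   `er_negative`, `triple_negative`), with attribute `excluded` (row
#'   indices with unknown ER).
#' @export
assign_subtype <- function(markers, disjoint = FALSE) {
  stopifnot(all(c("er", "pr", "her2") %in% names(markers)))
  er <- as.character(markers$er)
  pr <- as.character(markers$pr)
  her2 <- as.character(markers$her2)
  known <- er %in% c("+", "-")
  tn <- known & er == "-" & pr == "-" & her2 == "-"
  out <- data.frame(
    er_positive = known & er == "+",
    er_negative = known & er == "-" & !(disjoint & tn),
    triple_negative = tn
  )
  excluded <- which(!known)
  if (length(excluded)) {
    out[excluded, ] <- FALSE
    message(length(excluded), " patient(s) with unknown ER status excluded")
  }
  attr(out, "excluded") <- excluded
  out
}

# exact Spearman rho with average ranks for ties
spearman_rho <- function(x, y) {
  ok <- complete.cases(x, y)
  if (sum(ok) < 3) return(NA_real_)
  rx <- rank(x[ok]); ry <- rank(y[ok])
  if (sd(rx) == 0 || sd(ry) == 0) return(NA_real_)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

#' Screen genes by Spearman correlation with a feature
#'
#' Computes the Spearman correlation of every gene's transcription level
#' with the per-patient feature and returns genes with `|rho|` above the
#' threshold, sorted by `|rho|` descending (ties broken by gene symbol).
#' The correlation sign is retained in the output.
#'
#' @param feature named numeric vector (names = patient ids) or plain
#'   vector aligned with the expression columns.
#' @param expr genes x patients numeric matrix with rownames.
#' @param threshold selection threshold on `|rho|` (default 0.3).
#' @return data frame `gene, rho, abs_rho` of selected genes; attribute
#'   `all` holds the full table. A constant feature yields an empty result
#'   with a warning.
#' @export
spearman_screen <- function(feature, expr, threshold = 0.3) {
  if (!is.null(names(feature)) && !is.null(colnames(expr))) {
    common <- intersect(names(feature), colnames(expr))
    feature <- feature[common]
    expr <- expr[, common, drop = FALSE]
  }
  if (ncol(expr) < 3) stop("need at least 3 paired observations")
  if (length(unique(feature)) == 1L) {
    warning("constant feature: all correlations undefined")
    res <- data.frame(gene = character(0), rho = numeric(0),
                      abs_rho = numeric(0))
    attr(res, "all") <- res
    return(res)
  }
  rf <- rank(feature)
  rho <- apply(expr, 1, function(g) spearman_rho(rf, g))
  all_tab <- data.frame(gene = rownames(expr), rho = rho,
                        abs_rho = abs(rho), row.names = NULL)
  sel <- all_tab[!is.na(all_tab$rho) & all_tab$abs_rho > threshold, ]
  sel <- sel[order(-sel$abs_rho, sel$gene), ]
  rownames(sel) <- NULL
  attr(sel, "all") <- all_tab
  sel
}

#' Rank-sum tests of a score between mutated and wild-type patients
#'
#' Per gene, a two-sided Wilcoxon rank-sum test of the score between
#' carriers and non-carriers of a nonsynonymous mutation; genes mutated in
#' fewer than `min_mutated` patients (default 10) are excluded, as are
#' genes mutated in all patients (logged).
#'
#' @param til named numeric score vector (names = patient ids) or aligned
#'   vector.
#' @param mut genes x patients binary matrix.
#' @param min_mutated minimum carrier count (default 10).
#' @param exact use the exact test for small groups without ties (default:
#'   chosen by `wilcox.test`'s standard rule).
#' @return data frame `gene, n_mut, n_wt, statistic, p`; attribute
#'   `skipped` lists genes mutated in every patient.
#' @export
mutation_test <- function(til, mut, min_mutated = 10, exact = NULL) {
  if (min_mutated < 1) stop("min_mutated must be >= 1")
  if (!is.null(names(til)) && !is.null(colnames(mut))) {
    common <- intersect(names(til), colnames(mut))
    til <- til[common]
    mut <- mut[, common, drop = FALSE]
  }
  counts <- rowSums(mut > 0)
  skipped <- rownames(mut)[counts == ncol(mut)]
  if (length(skipped)) {
    message("gene(s) mutated in all patients skipped: ",
            paste(skipped, collapse = ", "))
  }
  keep <- which(counts >= min_mutated & counts < ncol(mut))
  res <- do.call(rbind, lapply(keep, function(gi) {
    grp <- mut[gi, ] > 0
    wt <- suppressWarnings(
      wilcox.test(til[grp], til[!grp], exact = exact)
    )
    data.frame(gene = rownames(mut)[gi], n_mut = sum(grp),
               n_wt = sum(!grp), statistic = unname(wt$statistic),
               p = wt$p.value)
  }))
  if (is.null(res)) {
    res <- data.frame(gene = character(0), n_mut = integer(0),
                      n_wt = integer(0), statistic = numeric(0),
                      p = numeric(0))
  }
  rownames(res) <- NULL
  attr(res, "skipped") <- skipped
  res
}

#' Two-group log-rank test
#'
#' The standard one-degree-of-freedom log-rank statistic: at every distinct
#' event time the observed group-A events are compared with their
#' hypergeometric expectation given the risk sets, with the usual
#' tie-corrected variance; `chisq = (sum(O - E))^2 / sum(V)`.
#'
#' @param timesA,eventsA,timesB,eventsB survival times and event indicators
#'   (1 = event, 0 = censored) for the two groups (both nonempty).
#' @return `list(chisq, p, obsA, expA)`; `p` is `NA` (flagged via
#'   `no_events`) when neither group has any event.
#' @export
logrank_test <- function(timesA, eventsA, timesB, eventsB) {
  if (length(timesA) == 0 || length(timesB) == 0) {
    stop("both groups must be nonempty")
  }
  time <- c(timesA, timesB)
  event <- c(eventsA, eventsB) > 0
  grpA <- rep(c(TRUE, FALSE), c(length(timesA), length(timesB)))
  if (!any(event)) {
    return(list(chisq = NA_real_, p = NA_real_, obsA = 0, expA = 0,
                no_events = TRUE))
  }
  eventtimes <- sort(unique(time[event]))
  O <- E <- V <- 0
  for (t in eventtimes) {
    at_risk <- time >= t
    n <- sum(at_risk)
    nA <- sum(at_risk & grpA)
    d <- sum(event & time == t)
    dA <- sum(event & time == t & grpA)
    O <- O + dA
    E <- E + d * nA / n
    if (n > 1) {
      V <- V + d * (nA / n) * (1 - nA / n) * (n - d) / (n - 1)
    }
  }
  if (V <= 0) {
    return(list(chisq = NA_real_, p = NA_real_, obsA = O, expA = E,
                no_events = FALSE))
  }
  chisq <- (O - E)^2 / V
  list(chisq = chisq, p = pchisq(chisq, df = 1, lower.tail = FALSE),
       obsA = O, expA = E, no_events = FALSE)
}

#' Percentile cutoff scan for univariate survival stratification
#'
#' For every percentile cutoff from `lo` to `hi` (step `step`; defaults
#' 20..80 by 1, 61 cutoffs) the cohort is split at the feature quantile and
#' the two groups compared by log-rank. The scan table carries one row per
#' cutoff; cutoffs producing identical splits are flagged and deduplicated
#' for the reported best cutoff (minimum p over distinct, nondegenerate
#' splits). No multiple-testing correction is applied to the reported
#' minimum p (matching the reference procedure); the scan table carries a
#' Benjamini-Hochberg column as a safety rail.
#'
#' @param feature per-patient numeric feature.
#' @param time,event survival times and event indicators.
#' @param lo,hi,step percentile range and increment.
#' @return object of class `cutoff_scan`: `best` (cutoff percentile, value,
#'   p), `scan` (the full table), `n_distinct` splits.
#' @export
univariate_cutoff_scan <- function(feature, time, event, lo = 20, hi = 80,
                                   step = 1) {
  stopifnot(length(feature) == length(time), length(time) == length(event))
  if (length(unique(feature)) == 1L) {
    stop("constant feature: no valid cutoff")
  }
  pcts <- seq(lo, hi, by = step)
  qs <- quantile(feature, pcts / 100, names = FALSE)
  scan <- data.frame(percentile = pcts, cutoff = qs,
                     n_low = NA_integer_, n_high = NA_integer_,
                     chisq = NA_real_, p = NA_real_, duplicate = FALSE)
  seen <- character(0)
  for (i in seq_along(pcts)) {
    low <- feature <= qs[i]
    scan$n_low[i] <- sum(low)
    scan$n_high[i] <- sum(!low)
    key <- paste(which(low), collapse = ",")
    if (key %in% seen) {
      scan$duplicate[i] <- TRUE
    }
    seen <- c(seen, key)
    if (scan$n_low[i] == 0 || scan$n_high[i] == 0) next
    lr <- logrank_test(time[low], event[low], time[!low], event[!low])
    scan$chisq[i] <- lr$chisq
    scan$p[i] <- lr$p
  }
  ok <- !scan$duplicate & !is.na(scan$p)
  scan$p_bh <- NA_real_
  scan$p_bh[ok] <- stats::p.adjust(scan$p[ok], method = "BH")
  if (!any(ok)) stop("no valid cutoff produced two nonempty groups")
  best_i <- which(ok)[which.min(scan$p[ok])]
  structure(list(
    best = list(percentile = scan$percentile[best_i],
                cutoff = scan$cutoff[best_i], p = scan$p[best_i],
                chisq = scan$chisq[best_i]),
    scan = scan,
    n_distinct = sum(!scan$duplicate),
    groups = feature <= scan$cutoff[best_i]
  ), class = "cutoff_scan")
}

#' @method print cutoff_scan
#' @export
print.cutoff_scan <- function(x, ...) {
  cat(sprintf("<cutoff_scan: best at %g percentile (p = %.3g; %d cutoffs, %d distinct)>\n",
              x$best$percentile, x$best$p, nrow(x$scan), x$n_distinct))
  invisible(x)
}

#' K-means risk groups with log-rank comparison
#'
#' Standardizes the feature matrix, clusters patients by seeded K-means
#' (with restarts) into `k` groups (default 2: high/low risk), and tests
#' the survival difference by log-rank (two groups). A degenerate cluster
#' (fewer than 2 members) triggers re-runs with new derived seeds, then a
#' flag.
#'
#' @param features patients x features numeric matrix.
#' @param time,event survival data.
#' @param k number of clusters (default 2).
#' @param seed RNG seed.
#' @param nstart K-means restarts.
#' @return `list(cluster, p, chisq, centers, degenerate)`.
#' @export
multivariate_risk_groups <- function(features, time, event, k = 2L,
                                     seed = 1L, nstart = 10L) {
  X <- scale(as.matrix(features))
  X[is.nan(X)] <- 0 # constant columns carry no information
  degenerate <- FALSE
  for (attempt in 1:3) {
    km <- with_seed(derive_seed(seed, paste0("kmeans", attempt)),
                    kmeans(X, centers = k, nstart = nstart, iter.max = 100))
    if (min(table(km$cluster)) >= 2) break
    if (attempt == 3) degenerate <- TRUE
  }
  p <- chisq <- NA_real_
  if (k == 2L) {
    g1 <- km$cluster == 1
    lr <- logrank_test(time[g1], event[g1], time[!g1], event[!g1])
    p <- lr$p; chisq <- lr$chisq
  } else {
    sd <- survival::survdiff(survival::Surv(time, event) ~ factor(km$cluster))
    chisq <- sd$chisq
    p <- pchisq(chisq, df = k - 1, lower.tail = FALSE)
  }
  list(cluster = km$cluster, p = p, chisq = chisq, centers = km$centers,
       degenerate = degenerate)
}

#' Lasso-Cox feature selection
#'
#' L1-penalized Cox regression along a penalty path with the penalty chosen
#' by cross-validated partial likelihood (seeded folds); features with
#' nonzero coefficients at the chosen penalty are returned with their
#' signs. Ties handled by Breslow's method (glmnet's convention).
#'
#' @param features patients x features numeric matrix (>= 2 columns).
#' @param time,event survival data (events must be present).
#' @param seed RNG seed for fold assignment.
#' @param nfolds cross-validation folds.
#' @param lambda `"lambda.1se"` (default, sparser) or `"lambda.min"`.
#' @return data frame `feature, coefficient` of selected features;
#'   attribute `fit` carries the `cv.glmnet` object.
#' @export
lasso_cox_select <- function(features, time, event, seed = 1L, nfolds = 10L,
                             lambda = c("lambda.1se", "lambda.min")) {
  lambda <- match.arg(lambda)
  X <- as.matrix(features)
  if (ncol(X) < 2) stop("need at least 2 features")
  if (sum(event) == 0) stop("no events: Cox model undefined")
  # exact duplicate columns make the L1 solution non-unique; keep the first
  # of each duplicate group so the selected set contains at most one
  dup <- duplicated(t(X))
  if (any(dup)) {
    message("dropping ", sum(dup), " duplicated feature column(s): ",
            paste(colnames(X)[dup], collapse = ", "))
    X <- X[, !dup, drop = FALSE]
  }
  y <- survival::Surv(time, event)
  foldid <- with_seed(derive_seed(seed, "lassofolds"),
                      sample(rep(seq_len(nfolds), length.out = nrow(X))))
  cv <- glmnet::cv.glmnet(X, y, family = "cox", foldid = foldid)
  co <- as.matrix(stats::coef(cv, s = lambda))
  nz <- which(co[, 1] != 0)
  res <- data.frame(feature = rownames(co)[nz], coefficient = co[nz, 1],
                    row.names = NULL)
  attr(res, "fit") <- cv
  attr(res, "lambda") <- lambda
  res
}
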