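# Synthetic patient cohort with planted gene-TIL correlations, mutation-TIL
# shifts and a feature-survival effect, so the association and survival
# procedures can be validated against known ground truth.

#' Specification for a synthetic cohort
#'
#' The generator works on a latent standard-normal "immune infiltration"
#' axis per patient. The TIL score is a fixed monotone transform of that
#' axis (so rank statistics are unaffected), planted genes correlate with it
#' via a Gaussian copula calibrated to the requested Spearman rho
#' (`pearson r = 2 sin(pi rho / 6)`), and planted mutations shift the axis
#' by `mut_effect` latent standard deviations.
#'
#' @param n_patients number of patients.
#' @param n_genes expression genes in total.
#' @param n_correlated_genes leading genes given the planted correlation.
#' @param planted_rho target Spearman correlation with the TIL score
#'   (`|rho| < 1`), default 0.6.
#' @param n_mut_genes mutation-matrix genes with a planted TIL shift; each
#'   is mutated in at least 10 patients (requires `n_patients >= 40`).
#' @param n_mut_null extra mutation genes with no effect and small random
#'   mutation counts (some below 10, to exercise the frequency filter).
#' @param mut_effect latent-SD shift of the TIL axis per planted mutation.
#' @param surv_feature name of the column driving survival (default
#'   `"til_score"`; any generated `feat_*` column may be named).
#' @param surv_feature_effect hazard ratio per SD of the survival feature
#'   (linear model) or between groups (threshold model).
#' @param surv_model `"linear"` proportional hazards on the standardized
#'   feature, or `"threshold"` (hazard steps at `threshold_percentile`).
#' @param threshold_percentile percentile (0-100) of the feature where the
#'   threshold-model hazard steps; default 40.
#' @param n_noise_features extra standard-normal feature columns.
#' @param censoring_rate expected fraction censored, in `[0, 1)`.
#' @param seed RNG seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 200, n_genes = 500,
                        n_correlated_genes = 20, planted_rho = 0.6,
                        n_mut_genes = 2, n_mut_null = 20, mut_effect = 0,
                        surv_feature = "til_score", surv_feature_effect = 1,
                        surv_model = "linear", threshold_percentile = 40,
                        n_noise_features = 5,
                        censoring_rate = 0.2, seed = 1L) {
  assert_scalar_num(n_patients, "n_patients", 10)
  assert_scalar_num(n_genes, "n_genes", 0)
  assert_scalar_num(n_correlated_genes, "n_correlated_genes", 0, n_genes)
  assert_scalar_num(censoring_rate, "censoring_rate", 0, 1 - 1e-9)
  if (abs(planted_rho) >= 1) stop("planted correlation must satisfy |rho| < 1")
  assert_scalar_num(surv_feature_effect, "surv_feature_effect", 1e-9)
  surv_model <- match.arg(surv_model, c("linear", "threshold"))
  structure(as.list(environment()), class = "cohort_spec")
}

#' Generate a synthetic cohort table
#'
#' @param spec a [cohort_spec].
#' @return object of class `til_cohort`: list with `clinical` (data frame:
#'   `patient_id, er, pr, her2, time, event, til_score, feat_*`),
#'   `expression` (genes x patients), `mutation` (binary genes x patients),
#'   and `truth` (planted gene names, mutation genes, survival feature).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_patients
  with_seed(spec$seed, {
    ids <- sprintf("P%04d", seq_len(n))

    # latent infiltration axis + planted mutation shifts
    latent0 <- rnorm(n)
    mut_genes <- if (spec$n_mut_genes > 0) {
      sprintf("MUTG%02d", seq_len(spec$n_mut_genes))
    } else character(0)
    mut_null <- if (spec$n_mut_null > 0) {
      sprintf("MUTN%02d", seq_len(spec$n_mut_null))
    } else character(0)
    mutation <- matrix(0L, length(mut_genes) + length(mut_null), n,
                       dimnames = list(c(mut_genes, mut_null), ids))
    latent <- latent0
    n_mut_carriers <- min(n - 2L, max(12L, ceiling(0.06 * n)))
    for (g in mut_genes) {
      carriers <- sample.int(n, n_mut_carriers)
      mutation[g, carriers] <- 1L
      latent[carriers] <- latent[carriers] + spec$mut_effect
    }
    for (g in mut_null) {
      k <- sample(3:max(4, ceiling(0.12 * n)), 1)
      mutation[g, sample.int(n, k)] <- 1L
    }
    til <- stats::plogis(latent - 1) * 0.6 # monotone map to a TIL% scale

    # expression: planted genes share the latent axis through a normal copula
    genes <- sprintf("GENE%04d", seq_len(spec$n_genes))
    expression <- matrix(NA_real_, spec$n_genes, n,
                         dimnames = list(genes, ids))
    r <- 2 * sin(pi * spec$planted_rho / 6)
    k_cor <- spec$n_correlated_genes
    if (spec$n_genes > 0) {
      for (gi in seq_len(spec$n_genes)) {
        z <- if (gi <= k_cor) {
          r * latent + sqrt(1 - r^2) * rnorm(n)
        } else {
          rnorm(n)
        }
        expression[gi, ] <- exp(2 + z) # lognormal-like transcription levels
      }
    }

    # markers -> subtypes with realistic frequencies
    er <- ifelse(runif(n) < 0.65, "+", "-")
    pr <- ifelse(er == "+", ifelse(runif(n) < 0.7, "+", "-"),
                 ifelse(runif(n) < 0.3, "+", "-"))
    her2 <- ifelse(er == "+", ifelse(runif(n) < 0.2, "+", "-"),
                   ifelse(runif(n) < 0.4, "+", "-"))

    feats <- matrix(rnorm(n * spec$n_noise_features), n,
                    dimnames = list(NULL, sprintf("feat_%d",
                                                  seq_len(spec$n_noise_features))))
    clinical <- data.frame(patient_id = ids, er = er, pr = pr, her2 = her2,
                           til_score = til, stringsAsFactors = FALSE)
    clinical <- cbind(clinical, as.data.frame(feats))

    # survival from a proportional-hazards model on the designated feature
    if (!spec$surv_feature %in% names(clinical)) {
      stop("unknown survival feature: ", spec$surv_feature)
    }
    x <- clinical[[spec$surv_feature]]
    xs <- as.numeric(scale(x))
    base_rate <- 1 / 1500 # baseline hazard, per day
    beta <- log(spec$surv_feature_effect)
    rate <- if (spec$surv_model == "linear") {
      base_rate * exp(beta * xs)
    } else {
      thr <- quantile(x, spec$threshold_percentile / 100, names = FALSE)
      base_rate * exp(beta * (x > thr))
    }
    t_event <- rexp(n, rate)
    if (spec$censoring_rate > 0) {
      c_rate <- base_rate * spec$censoring_rate / (1 - spec$censoring_rate)
      t_cens <- rexp(n, c_rate)
      clinical$time <- pmin(t_event, t_cens)
      clinical$event <- as.integer(t_event <= t_cens)
    } else {
      clinical$time <- t_event
      clinical$event <- 1L
    }

    structure(list(
      clinical = clinical, expression = expression, mutation = mutation,
      truth = list(correlated_genes = genes[seq_len(k_cor)],
                   planted_rho = spec$planted_rho,
                   mut_genes = mut_genes,
                   surv_feature = spec$surv_feature,
                   surv_model = spec$surv_model,
                   threshold_percentile = spec$threshold_percentile),
      spec = spec
    ), class = "til_cohort")
  })
}

#' @method print til_cohort
#' @export
print.til_cohort <- function(x, ...) {
  cat(sprintf("<til_cohort: %d patients, %d genes, %d mutation genes>\n",
              nrow(x$clinical), nrow(x$expression), nrow(x$mutation)))
  invisible(x)
}

#' Write a cohort to CSV files
#'
#' @param cohort a `til_cohort`.
#' @param dir output directory.
#' @return written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- file.path(dir, c("clinical.csv", "expression.csv", "mutation.csv"))
  write_csv_meta(cohort$clinical, p[1], seed = cohort$spec$seed)
  write_csv_meta(data.frame(gene = rownames(cohort$expression),
                            cohort$expression, check.names = FALSE), p[2])
  write_csv_meta(data.frame(gene = rownames(cohort$mutation),
                            cohort$mutation, check.names = FALSE), p[3])
  invisible(p)
}

#' Read a cohort written by [write_cohort()]
#' @param dir directory holding `clinical.csv`, `expression.csv`,
#'   `mutation.csv`.
#' @return a `til_cohort` (without generator truth).
#' @export
read_cohort <- function(dir) {
  clinical <- read_csv_meta(file.path(dir, "clinical.csv"))
  rd <- function(f) {
    df <- read_csv_meta(file.path(dir, f))
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    colnames(m) <- names(df)[-1]
    m
  }
  structure(list(clinical = clinical, expression = rd("expression.csv"),
                 mutation = rd("mutation.csv"), truth = NULL, spec = NULL),
            class = "til_cohort")
}
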