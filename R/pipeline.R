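# End-to-end orchestration: slide -> FOV -> TIL map -> feature vector, and
# cohort-level association/survival reports. A single top-level seed drives
# every stage through derive_seed(); every output directory receives the
# resolved configuration and a JSON-lines stage log.

#' Default pipeline configuration
#'
#' @param seed top-level seed; all stage seeds derive from it.
#' @param downsample_factor field-of-view downsampling (default 16).
#' @param k_tissue K-means groups for tissue clustering (default 3).
#' @param patch_size tile size (default 200).
#' @param max_background maximum background fraction of a valid patch.
#' @param min_fraction TIL-patch selection threshold.
#' @param damping,preference affinity propagation parameters.
#' @param spearman_threshold expression screen threshold on `|rho|`.
#' @param min_mutated mutation-test carrier filter.
#' @param scan_lo,scan_hi,scan_step cutoff-scan percentiles.
#' @param verbose print stage messages.
#' @return named list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, downsample_factor = 16L,
                            k_tissue = 3L, patch_size = 200L,
                            max_background = 0.8, min_fraction = 0.1,
                            damping = 0.9, preference = "median",
                            spearman_threshold = 0.3, min_mutated = 10L,
                            scan_lo = 20, scan_hi = 80, scan_step = 1,
                            verbose = FALSE) {
  structure(as.list(environment()), class = "pipeline_config")
}

config_hash <- function(cfg) {
  s <- paste(names(cfg), vapply(cfg, function(x) paste(format(x), collapse = ","),
                                ""), collapse = ";")
  # small stable string hash (FNV-style, mod 2^31-1)
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 131 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}

log_stage <- function(con, stage, status, ...) {
  rec <- c(list(ts = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                stage = stage, status = status), list(...))
  writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
}

#' Run the slide pipeline end to end
#'
#' FOV identification, tiling, TIL map, TIL score and spatial features, all
#' intermediates persisted under `out_dir`. Re-running with the same seed
#' reproduces identical outputs.
#'
#' @param slide a [raster_slide] or path to a `.ppm` slide.
#' @param ckpt a `seg_checkpoint` or path prefix for [load_checkpoint()].
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created).
#' @param slide_id identifier used in logs and outputs.
#' @return `list(fov, map, features)`, invisibly; outputs on disk:
#'   `fov.json`, `til_map.csv`, `features.csv`, `clusters.csv`,
#'   `config.json`, `log.jsonl`.
#' @export
run_slide <- function(slide, ckpt, config = pipeline_config(),
                      out_dir = tempfile("tilscope_"), slide_id = "slide") {
  if (is.character(slide)) slide <- read_slide(slide)
  if (is.character(ckpt)) ckpt <- load_checkpoint(ckpt)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file(file.path(out_dir, "log.jsonl"), "w")
  on.exit(close(logf))
  jsonlite::write_json(c(unclass(config), list(config_hash = config_hash(config))),
                       file.path(out_dir, "config.json"), auto_unbox = TRUE)
  say <- function(...) if (isTRUE(config$verbose)) message(...)

  stage <- "fov"
  res <- tryCatch({
    fov <- identify_fov(slide, factor = config$downsample_factor,
                        k = config$k_tissue,
                        seed = derive_seed(config$seed, "fov"))
    write_fov(fov, file.path(out_dir, "fov.json"))
    log_stage(logf, "fov", "ok", slide = slide_id,
              bbox = as.integer(fov$bbox_full))
    say("FOV: ", paste(fov$bbox_full, collapse = " "))

    stage <- "tiling"
    crop <- crop_fov(slide, fov)
    grid <- tile_fov(crop, patch_size = config$patch_size, fov = fov,
                     max_background = config$max_background)
    log_stage(logf, "tiling", "ok", slide = slide_id, K = grid$K)

    stage <- "til_map"
    map <- compute_til_map(ckpt, grid, crop)
    write_til_map(map, file.path(out_dir, "til_map.csv"), seed = config$seed)
    score <- til_score(map)
    log_stage(logf, "til_map", "ok", slide = slide_id, til_score = score)
    say(sprintf("TIL%% = %.4f over %d valid patches", score, map$K))

    stage <- "features"
    fv <- compute_feature_vector(map, min_fraction = config$min_fraction,
                                 preference = config$preference,
                                 damping = config$damping)
    write_feature_vector(fv, file.path(out_dir, "features.csv"),
                         slide_id = slide_id, seed = config$seed)
    write_clusters(fv, file.path(out_dir, "clusters.csv"))
    log_stage(logf, "features", "ok", slide = slide_id,
              k = if (is.null(fv$clustering)) NA else fv$clustering$k)
    list(fov = fov, map = map, features = fv)
  }, error = function(e) {
    log_stage(logf, stage, "error", slide = slide_id,
              message = conditionMessage(e))
    stop(sprintf("[%s] stage '%s': %s", slide_id, stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(res)
}

#' Run the cohort-level association and survival analyses
#'
#' Per subtype (ER-positive, ER-negative, triple-negative): the Spearman
#' expression screen against the TIL score, the mutation rank-sum tests,
#' the univariate cutoff scan and the K-means + Lasso-Cox multivariate
#' procedure on the feature columns. Patients with ids missing from any
#' table are listed and excluded; an empty subtype is skipped with a
#' warning.
#'
#' @param cohort a `til_cohort` (or a directory readable by
#'   [read_cohort()]).
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @param feature_cols clinical columns used as survival features; default
#'   `til_score` plus every `feat_*` column.
#' @return nested list of per-subtype results, invisibly; CSV reports under
#'   `out_dir/<subtype>/`.
#' @export
run_cohort <- function(cohort, config = pipeline_config(),
                       out_dir = tempfile("tilscope_cohort_"),
                       feature_cols = NULL) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file(file.path(out_dir, "log.jsonl"), "w")
  on.exit(close(logf))
  jsonlite::write_json(c(unclass(config), list(config_hash = config_hash(config))),
                       file.path(out_dir, "config.json"), auto_unbox = TRUE)

  cl <- cohort$clinical
  ids <- cl$patient_id
  miss_e <- setdiff(ids, colnames(cohort$expression))
  miss_m <- setdiff(ids, colnames(cohort$mutation))
  excl <- union(miss_e, miss_m)
  if (length(excl)) {
    log_stage(logf, "id_check", "warn", excluded = excl)
    warning("excluding ", length(excl), " patient(s) with missing omics: ",
            paste(head(excl, 5), collapse = ", "))
    cl <- cl[!cl$patient_id %in% excl, ]
  }
  feature_cols <- feature_cols %||%
    c("til_score", grep("^feat_", names(cl), value = TRUE))

  sub <- assign_subtype(cl)
  out <- list()
  for (st in c("er_positive", "er_negative", "triple_negative")) {
    members <- which(sub[[st]])
    if (length(members) < 10) {
      warning("subtype ", st, " has ", length(members),
              " patients; report skipped")
      log_stage(logf, st, "skipped", n = length(members))
      next
    }
    d <- cl[members, ]
    sdir <- file.path(out_dir, st)
    dir.create(sdir, showWarnings = FALSE)
    til <- setNames(d$til_score, d$patient_id)

    screen <- spearman_screen(til, cohort$expression[, d$patient_id,
                                                     drop = FALSE],
                              threshold = config$spearman_threshold)
    write_csv_meta(screen, file.path(sdir, "spearman_screen.csv"),
                   seed = config$seed)

    mt <- mutation_test(til, cohort$mutation[, d$patient_id, drop = FALSE],
                        min_mutated = config$min_mutated)
    write_csv_meta(mt, file.path(sdir, "mutation_test.csv"),
                   seed = config$seed)

    scans <- lapply(feature_cols, function(fc) {
      tryCatch(univariate_cutoff_scan(d[[fc]], d$time, d$event,
                                      lo = config$scan_lo,
                                      hi = config$scan_hi,
                                      step = config$scan_step),
               error = function(e) NULL)
    })
    names(scans) <- feature_cols
    best <- do.call(rbind, lapply(feature_cols, function(fc) {
      s <- scans[[fc]]
      if (is.null(s)) return(NULL)
      data.frame(feature = fc, percentile = s$best$percentile,
                 cutoff = s$best$cutoff, p = s$best$p)
    }))
    if (!is.null(best)) {
      write_csv_meta(best, file.path(sdir, "univariate_survival.csv"),
                     seed = config$seed)
    }

    Xf <- as.matrix(d[, feature_cols, drop = FALSE])
    mg <- multivariate_risk_groups(Xf, d$time, d$event, k = 2L,
                                   seed = derive_seed(config$seed, st))
    lasso <- tryCatch(
      lasso_cox_select(Xf, d$time, d$event,
                       seed = derive_seed(config$seed, paste0(st, "lasso"))),
      error = function(e) NULL)
    if (!is.null(lasso)) {
      write_csv_meta(lasso, file.path(sdir, "lasso_selected.csv"),
                     seed = config$seed)
    }
    km_df <- data.frame(patient_id = d$patient_id, risk_group = mg$cluster)
    write_csv_meta(km_df, file.path(sdir, "risk_groups.csv"),
                   seed = config$seed)
    log_stage(logf, st, "ok", n = nrow(d), screen_hits = nrow(screen),
              mut_genes = nrow(mt), km_p = mg$p)
    out[[st]] <- list(screen = screen, mutation = mt, scans = scans,
                      risk_groups = mg, lasso = lasso)
  }
  invisible(out)
}

#' Kaplan-Meier step coordinates for plotting
#'
#' @param time,event survival data for one group.
#' @return data frame `time, surv` of step coordinates (product-limit
#'   estimate).
#' @export
km_curve <- function(time, event) {
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  data.frame(time = fit$time, surv = fit$surv)
}
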