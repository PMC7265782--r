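digest_key <- function(p) {
  paste(c(dim(p$pixels), round(as.numeric(p$centers), 4),
          p$pixels[1:50]), collapse = "|")
}

test_that("generate_slide handles the empty, deterministic and invalid cases", {
  spec0 <- test_slide_spec(seed = 3, lymph_density = 0)
  g0 <- generate_slide(spec0)
  expect_equal(nrow(g0$truth$lymph_centers), 0L)

  spec <- test_slide_spec(seed = 7)
  g1 <- generate_slide(spec)
  g2 <- generate_slide(spec)
  expect_identical(g1$slide$pixels, g2$slide$pixels)
  expect_identical(g1$truth$lymph_centers, g2$truth$lymph_centers)

  expect_error(
    slide_spec(width = 400, height = 400,
               tissue_blobs = list(list(center = c(390, 200), radius = 100,
                                        color = c(226, 158, 180)))),
    "outside"
  )
})

test_that("lymphocyte counts follow the Poisson intensity (mean oracle over seeds)", {
  # one blob, intensity tuned so the expected count is 100; the blob is
  # large enough that hard-core interaction is negligible
  blob <- list(list(center = c(500, 500), radius = 450,
                    color = c(226, 158, 180)))
  area <- sum(tilscope:::render_tissue_mask(
    slide_spec(width = 1000, height = 1000, tissue_blobs = blob)))
  lambda <- 100 / area
  counts <- vapply(1:40, function(s) {
    spec <- slide_spec(width = 1000, height = 1000, tissue_blobs = blob,
                       lymph_density = lambda, noise_sd = 0,
                       distractor_density = 0, seed = s)
    nrow(generate_slide(spec)$truth$lymph_centers)
  }, 0)
  # each draw within 4.5 sd of 100; the mean within ~3 sd / sqrt(nseeds)
  # (a residual percent-level deficit from hard-core thinning is tolerated)
  expect_true(all(abs(counts - 100) <= 4.5 * sqrt(100)))
  expect_lt(abs(mean(counts) - 100), 3 * sqrt(100) / sqrt(length(counts)) + 2)
})

test_that("rendered nuclei lie inside the tissue mask", {
  for (s in 1:3) {
    g <- generate_slide(test_slide_spec(seed = s, lymph_density = 4e-4))
    ctr <- g$truth$lymph_centers
    expect_gt(nrow(ctr), 0)
    discs <- centers_to_mask(ctr, dim(g$truth$tissue_mask), 32)
    expect_true(all(g$truth$tissue_mask[discs]))
  }
})

test_that("annotated patches cover the empty, split and expectation cases", {
  spec0 <- test_slide_spec(seed = 2, lymph_density = 0)
  a0 <- generate_annotated_patches(10, spec0)
  expect_length(a0$patches, 10L)
  expect_true(all(vapply(a0$patches, function(p) nrow(p$centers), 0L) == 0L))
  expect_true(all(vapply(a0$patches, function(p)
    identical(dim(p$pixels), c(200L, 200L, 3L)), TRUE)))

  # D1-like geometry: 200 patches, 80/20 split, disjoint
  spec <- slide_spec(seed = 9)
  aps <- generate_annotated_patches(200, spec, seed = 9)
  sp <- split_patches(aps, 0.8, seed = 4)
  expect_length(sp$train$patches, 160L)
  expect_length(sp$test$patches, 40L)
  key <- function(p) paste(round(p$centers, 3), collapse = ",")
  k_tr <- vapply(sp$train$patches, function(p) digest_key(p), "")
  k_te <- vapply(sp$test$patches, function(p) digest_key(p), "")
  expect_length(intersect(k_tr, k_te), 0L)

  # total center count near the Poisson expectation (allowing thinning)
  total <- sum(vapply(aps$patches, function(p) nrow(p$centers), 0L))
  expected <- 200 * spec$lymph_density * 200^2
  expect_gt(total, expected * 0.85)
  expect_lt(total, expected * 1.15)
})

test_that("cohort generator plants correlations and honours censoring", {
  # censoring_rate = 0 -> every patient has an event
  co0 <- generate_cohort(cohort_spec(n_patients = 60, n_genes = 10,
                                     n_correlated_genes = 2,
                                     censoring_rate = 0, seed = 5))
  expect_true(all(co0$clinical$event == 1L))

  # planted rho = 0.6 recovered within 0.1 at n = 500 (3 seeds here;
  # the broader Monte-Carlo lives in the acceptance suite)
  for (s in 1:3) {
    co <- generate_cohort(cohort_spec(n_patients = 500, n_genes = 10,
                                      n_correlated_genes = 5,
                                      planted_rho = 0.6, seed = s))
    til <- co$clinical$til_score
    rho <- vapply(co$truth$correlated_genes, function(g) {
      cor(til, co$expression[g, ], method = "spearman")
    }, 0)
    expect_true(all(abs(rho - 0.6) < 0.1))
  }

  # planted rho = 0 -> null genes essentially never cross |rho| > 0.3
  con <- generate_cohort(cohort_spec(n_patients = 500, n_genes = 200,
                                     n_correlated_genes = 0, seed = 11))
  rho0 <- apply(con$expression, 1, function(g) {
    cor(con$clinical$til_score, g, method = "spearman")
  })
  expect_lte(sum(abs(rho0) > 0.3), 1L)

  # infeasible planting rejected
  expect_error(cohort_spec(planted_rho = 1), "rho")

  # planted mutation genes have >= 10 carriers
  expect_true(all(rowSums(co0$mutation[co0$truth$mut_genes, , drop = FALSE]) >= 10))

  # determinism
  expect_identical(generate_cohort(cohort_spec(seed = 8))$clinical,
                   generate_cohort(cohort_spec(seed = 8))$clinical)
})
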