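# Shared fixtures. Everything is generated in code; trained models are
# memoised so several test files can reuse one reference training run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, maker) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, maker(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# small slide spec used across tests (fast to render)
test_slide_spec <- function(seed = 1L, ...) {
  slide_spec(width = 800, height = 800, seed = seed, ...)
}

# reference desk-scale model: 48 training patches, 8 epochs (~25 s once)
ref_model <- function() {
  cached("ref_model", function() {
    spec <- slide_spec(seed = 501)
    aps <- generate_annotated_patches(60, spec, seed = 501)
    sp <- split_patches(aps, 0.8, seed = 501)
    ck <- train_model(seg_model_config(epochs = 8, seed = 501),
                      sp$train, sp$test)
    list(ckpt = ck, train = sp$train, test = sp$test, spec = spec)
  })
}

# a checkpoint that predicts (essentially) nothing everywhere
null_model <- function(base_width = 8L) {
  cfg <- seg_model_config(base_width = base_width)
  params <- tilscope:::init_params(cfg)
  params <- lapply(params, function(p) p * 0)
  params$final_b <- -10
  structure(list(params = params, config = cfg,
                 log = data.frame(epoch = integer(0),
                                  train_loss = numeric(0),
                                  val_loss = numeric(0)),
               stage = "U1"), class = "seg_checkpoint")
}

# construct a til_map container directly from Li/Ti vectors (row-major grid)
make_til_map <- function(Li, Ti, ncol_grid = length(Li)) {
  n <- length(Li)
  ncol_grid <- max(ncol_grid, 1L)
  ent <- data.frame(
    grid_row = (seq_len(n) - 1L) %/% ncol_grid,
    grid_col = (seq_len(n) - 1L) %% ncol_grid,
    r0 = ((seq_len(n) - 1L) %/% ncol_grid) * 200L,
    c0 = ((seq_len(n) - 1L) %% ncol_grid) * 200L,
    background_fraction = rep(0, n), valid = rep(TRUE, n),
    Li = as.numeric(Li), Ti = as.numeric(Ti),
    level = as.integer(ifelse(Ti > 0, round(250 * Li / Ti), 0))
  )
  structure(list(entries = ent, patch_size = 200L, K = n, mask = NULL,
                 crop_dim = c(200L * max(c(ent$grid_row, 0L) + 1L),
                              200L * ncol_grid)),
            class = "til_map")
}

# adjusted Rand index between two label vectors
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  exp_ <- si * sj / n2
  max_ <- (si + sj) / 2
  if (max_ == exp_) return(1)
  (sij - exp_) / (max_ - exp_)
}

# O(n^4) brute-force concordance oracle
bf_concordance <- function(X, lab) {
  D <- as.matrix(dist(X))
  n <- nrow(X)
  W <- c(); B <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (lab[i] == lab[j]) W <- c(W, D[i, j]) else B <- c(B, D[i, j])
  }
  sp <- 0; sm <- 0
  for (w in W) for (b in B) {
    if (w < b) sp <- sp + 1 else if (w > b) sm <- sm + 1
  }
  list(s_plus = sp, s_minus = sm, n_w = length(W), n_b = length(B))
}

# random detection instance mirroring the package's real use: ground-truth
# nuclei keep a hard-core separation (solid bodies), predictions are the
# truths under small localization jitter plus spurious detections - the
# "non-adversarial" world in which greedy matching attains the optimum
random_detection_instance <- function(seed, max_pts = 8, field = 120,
                                      min_sep = 36, jitter = 5) {
  set.seed(seed)
  nt <- sample(0:max_pts, 1)
  truth <- matrix(0, 0, 2)
  while (nrow(truth) < nt) {
    cand <- runif(2, 0, field)
    if (nrow(truth) == 0 ||
        min((truth[, 1] - cand[1])^2 + (truth[, 2] - cand[2])^2) >= min_sep^2) {
      truth <- rbind(truth, cand)
    }
  }
  keep <- if (nt > 0) runif(nt) < 0.85 else logical(0)
  pred <- truth[keep, , drop = FALSE]
  if (nrow(pred) > 0) {
    pred <- pred + matrix(pmax(pmin(rnorm(2 * nrow(pred), sd = jitter), 12),
                               -12), ncol = 2)
  }
  nfp <- sample(0:2, 1)
  if (nfp > 0) pred <- rbind(pred, matrix(runif(2 * nfp, 0, field), ncol = 2))
  list(pred = pred, truth = truth)
}

# exhaustive maximum bipartite matching size within radius (n <= 8)
bf_max_matching <- function(pred, truth, radius) {
  np <- nrow(pred); nt <- nrow(truth)
  if (np == 0 || nt == 0) return(0L)
  D <- sqrt(outer(pred[, 1], truth[, 1], `-`)^2 +
            outer(pred[, 2], truth[, 2], `-`)^2)
  ok <- D <= radius
  best <- 0L
  rec <- function(p, used, count) {
    if (count + (np - p + 1) <= best) return()
    if (p > np) { best <<- max(best, count); return() }
    rec(p + 1, used, count) # leave p unmatched
    for (t in seq_len(nt)) {
      if (ok[p, t] && !used[t]) {
        used[t] <- TRUE
        rec(p + 1, used, count + 1L)
        used[t] <- FALSE
      }
    }
  }
  rec(1L, rep(FALSE, nt), 0L)
  best
}
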