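test_that("low-count filter applies the smallest-group rule at the boundary", {
  counts <- rbind(g_all_zero = c(0L, 0L, 0L, 0L, 0L),
                  g_at_10 = c(5L, 5L, 50L, 50L, 50L),
                  g_at_11 = c(5L, 6L, 50L, 50L, 50L))
  groups <- c("small", "small", "big", "big", "big")
  kept <- filter_low_counts(counts, groups, min_count = 10)
  expect_identical(rownames(kept), "g_at_11")

  # idempotent and oracle-identical on a simulated cohort
  sim <- suppressWarnings(simulate_cohort_counts(cohort_config(
    n_genes = 1200, group_sizes = c(A = 5, B = 8), n_marker_genes = 50,
    n_shared_tumor_genes = 50, seed = 2)))
  grp <- sim$annotations$definition
  once <- filter_low_counts(sim$counts, grp)
  expect_identical(filter_low_counts(once, grp), once)
  smallest <- names(which.min(table(grp)))
  oracle <- sim$counts[apply(
    sim$counts[, grp == smallest, drop = FALSE], 1, sum) > 10, ]
  expect_identical(once, oracle)

  expect_error(filter_low_counts(counts, factor(groups, levels = c("small", "big", "ghost"))),
               "empty")
})

test_that("size factors are median-of-ratios with its scaling identities", {
  base <- matrix(rpois(600, 40), 100, 6,
                 dimnames = list(sprintf("g%02d", 1:100), sprintf("s%d", 1:6)))
  same <- base[, c(1, 1, 1)]
  colnames(same) <- c("a", "b", "c")
  expect_equal(unname(normalize_vst(same)$size_factors), c(1, 1, 1))

  doubled <- cbind(base, dbl = 2L * base[, 1])
  sf <- normalize_vst(doubled)$size_factors
  expect_equal(unname(sf["dbl"] / sf[1]), 2, tolerance = 1e-12)

  # scale equivariance: multiplying one sample by c multiplies its size factor
  # by c relative to the other samples (the pseudo-reference rescales, so the
  # invariant is stated on factor ratios, which is what the offsets use)
  scaled <- base
  scaled[, 3] <- scaled[, 3] * 5L
  sf0 <- normalize_vst(base)$size_factors
  sf1 <- normalize_vst(scaled)$size_factors
  expect_equal(unname((sf1[3] / sf1[1]) / (sf0[3] / sf0[1])), 5,
               tolerance = 1e-12)
})

test_that("the log2 transform flattens the NB SD-vs-mean trend", {
  sim <- nb_two_group(n_genes = 3000, n_per_group = 15, seed = 5)
  vst <- normalize_vst(sim$counts)$vst
  m <- rowMeans(vst)
  s <- sqrt(tripletrx:::row_vars(vst))
  upper <- m >= stats::median(m)
  slope <- stats::coef(stats::lm(s[upper] ~ m[upper]))[2]
  expect_lt(abs(slope), 0.1)
})

test_that("batch correction removes planted offsets and preserves biology", {
  set.seed(31)
  x <- matrix(rnorm(200 * 24, 8, 1), 200, 24,
              dimnames = list(sprintf("g%03d", 1:200), sprintf("s%02d", 1:24)))
  batch <- rep(c("b1", "b2"), 12)

  # single batch: unchanged
  expect_identical(correct_batch(x, rep("b1", 24)), x)

  # pure additive offset, no other structure: removed to machine precision
  # (corrected matrices agree up to a per-gene constant, which carries no
  # between-sample information)
  off <- rnorm(200, 0, 0.7)
  x_off <- x
  x_off[, batch == "b2"] <- x_off[, batch == "b2"] + off
  cor1 <- correct_batch(x_off, batch)
  cor0 <- correct_batch(x, batch)
  center <- function(m) m - rowMeans(m)
  expect_equal(center(cor1), center(cor0), tolerance = 1e-10)

  # orthogonal subtype effect preserved exactly
  subtype <- rep(c("t1", "t1", "t2", "t2"), 6)  # orthogonal to alternating batch
  x_bio <- x_off
  x_bio[1:50, subtype == "t2"] <- x_bio[1:50, subtype == "t2"] + 2
  corrected <- correct_batch(x_bio, batch,
                             covariates = data.frame(subtype = subtype))
  gm <- function(mat) rowMeans(mat[1:50, subtype == "t2"]) -
    rowMeans(mat[1:50, subtype == "t1"])
  expect_equal(gm(corrected), gm(x_bio) - 0, tolerance = 1e-9)

  # 1:1 confounding is refused
  conf <- rep(c("t1", "t2"), 12)  # identical partition to batch
  expect_error(correct_batch(x, batch, covariates = data.frame(subtype = conf)),
               "confounded")
})

test_that("variable-gene selection is top-n by variance with stable ties", {
  x <- matrix(c(rep(1, 4), 1:4, c(0, 0, 10, 10), c(5, 5, 5, 6), c(0, 4, 8, 12)),
              5, 4, byrow = TRUE,
              dimnames = list(c("flat", "ramp", "step", "blip", "steep"), NULL))
  top2 <- select_variable_genes(x, 2)
  expect_identical(rownames(top2), c("step", "steep"))  # variances 100/3, 80/3
  expect_identical(select_variable_genes(x, 5), x[order(-tripletrx:::row_vars(x),
                                                        rownames(x)), ])
  expect_identical(select_variable_genes(top2, 2), top2)  # idempotent
  expect_error(select_variable_genes(x, 6), "exceeds")
})

test_that("cluster-number diagnostics recover blobs and respect sample order", {
  set.seed(17)
  blobs <- cbind(matrix(rnorm(40 * 20, 0), 40, 20),
                 matrix(rnorm(40 * 20, 6), 40, 20))
  colnames(blobs) <- sprintf("s%02d", 1:40)
  cs <- kmeans_diagnostics(blobs, k_range = 2:6, gap_B = 10, seed = 1)
  expect_identical(cs$k, 2L)
  expect_identical(cs$selection_rule, "silhouette argmax")
  expect_identical(nrow(cs$diagnostics), 5L)
  expect_true(all(is.finite(cs$diagnostics$gap)))

  perm <- sample(40)
  cs_p <- kmeans_diagnostics(blobs[, perm], k_range = 2:6, gap_B = 10, seed = 1)
  expect_identical(cs_p$k, cs$k)
  expect_equal(adjusted_rand(cs_p$assignments, cs$assignments[perm]), 1)

  expect_error(kmeans_diagnostics(blobs[, 1:4], k_range = 2:6, gap_B = 5),
               "fewer samples")
})

test_that("gap statistic favors k = 1 on structureless data by the one-SE rule", {
  set.seed(23)
  flat <- matrix(runif(30 * 30), 30, 30)
  colnames(flat) <- sprintf("s%02d", 1:30)
  cs <- kmeans_diagnostics(flat, k_range = 2:6, gap_B = 25, seed = 7)
  expect_identical(cs$gap_k, 1L)
})

test_that("gap statistic agrees with the reference implementation's choice", {
  set.seed(29)
  # three well-separated blobs: both gap implementations should pick k = 3
  blobs <- cbind(matrix(rnorm(20 * 12, 0), 20, 12),
                 matrix(rnorm(20 * 12, 5), 20, 12),
                 matrix(rnorm(20 * 12, 10), 20, 12))
  colnames(blobs) <- sprintf("s%02d", seq_len(36))
  cs <- kmeans_diagnostics(blobs, k_range = 2:6, gap_B = 30, seed = 2)
  ref <- cluster::clusGap(t(blobs), FUN = function(x, k)
    stats::kmeans(x, k, nstart = 10, iter.max = 50), K.max = 6, B = 30,
    spaceH0 = "scaledPCA", verbose = FALSE)
  ref_k <- cluster::maxSE(ref$Tab[, "gap"], ref$Tab[, "SE.sim"],
                          method = "firstSEmax")
  expect_identical(cs$gap_k, as.integer(ref_k))
  expect_identical(cs$gap_k, 3L)
})

test_that("PCA embedding matches eigendecomposition and applies consistently", {
  set.seed(41)
  x <- matrix(rnorm(10 * 6), 10, 6,
              dimnames = list(sprintf("g%02d", 1:10), sprintf("s%d", 1:6)))
  pm <- fit_pca(x, 5)

  # orthonormal loadings, non-increasing explained variance
  expect_equal(crossprod(pm$rotation), diag(5), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_true(all(diff(pm$explained_var) <= 1e-12))

  # explained variances equal the brute-force covariance eigenvalues
  ev <- eigen(stats::cov(t(x)), symmetric = TRUE)$values
  expect_equal(pm$explained_var, (ev / sum(ev))[1:5], tolerance = 1e-10)

  # applying to the training data reproduces the scores; full rank reconstructs
  expect_equal(apply_pca(pm, x), pm$scores, tolerance = 1e-10)
  recon <- tcrossprod(pm$scores, pm$rotation) + rep(pm$center, each = 6)
  expect_lt(max(abs(t(recon) - x)), 1e-8)

  expect_error(fit_pca(x, 6), "exceeds")
})

test_that("shift projection recovers planted constant shifts", {
  set.seed(53)
  n <- 120; K <- 8
  sdev <- c(8, 6, 5, 4, 3, 2, 1.5, 1)
  orig <- sapply(sdev, function(s) rnorm(n, sd = s))
  rownames(orig) <- sprintf("s%03d", 1:n)
  shift <- c(1.5, -2, 1, 0.8, -1.2)
  repro <- orig
  for (j in 1:5) repro[, j] <- orig[, j] - shift[j] + rnorm(n, sd = 0.1)
  repro <- repro[, c(2, 1, 3:K)]  # swapped order...
  repro[, 1] <- -repro[, 1]       # ...and a sign flip

  model <- train_shift_projection(orig, repro, n_components = 5,
                                  n_predictors = K, seed = 3)
  # intercepts recover the planted shifts within CV noise
  intercepts <- vapply(model$models, `[[`, numeric(1), "intercept")
  expect_equal(intercepts, shift, tolerance = 0.1)

  mapped <- map_new_samples(model, repro)
  expect_lt(max(abs(mapped[, 1:5] - orig[, 1:5])), 0.5)

  # identity embeddings give a zero-shift model and an identity mapping
  triv <- train_shift_projection(orig, orig, n_components = 5,
                                 n_predictors = K, seed = 3)
  expect_equal(vapply(triv$models, `[[`, numeric(1), "intercept"), rep(0, 5))
  expect_equal(map_new_samples(triv, orig), orig, ignore_attr = TRUE)

  # uncorrelated embeddings are refused
  noise <- matrix(rnorm(n * K), n, K, dimnames = list(rownames(orig), NULL))
  expect_error(train_shift_projection(orig, noise, seed = 1),
               "not comparable")
  expect_error(map_new_samples(model, repro[, 1:4]), "dimension mismatch")
})

test_that("hand-built projection model applies exact arithmetic", {
  model <- structure(list(
    models = list(list(intercept = 1, beta = rep(0, 3), cv_error = 0)),
    alignment = list(perm = 1:3, signs = rep(1, 3), n_matched = 1L),
    n_components = 1L, n_predictors = 3L, cv_error = 0),
    class = "projection_model")
  coords <- matrix(seq_len(12), 4, 3)
  out <- map_new_samples(model, coords)
  expect_equal(out[, 1], coords[, 1] + 1)
  expect_equal(out[, 2:3], coords[, 2:3])
})

test_that("end-to-end projection corrects simulated cell lines toward their subtype", {
  sim <- simulate_cohort_counts(cohort_config(
    n_genes = 3000, group_sizes = c(A = 12, B = 20, C = 20, D = 20, E = 20),
    n_marker_genes = 150, n_shared_tumor_genes = 150,
    n_cell_lines = 12, seed = 21))
  is_cl <- sim$annotations$definition == "cell line"

  clinical <- sim$counts[, !is_cl]
  ann_cl <- sim$annotations[!is_cl, ]
  vg <- cohort_pipeline(list(counts = clinical, annotations = ann_cl), n_var = 1000)
  frozen <- fit_pca(vg, 10)

  # integrated reprocessing: clinical + cell lines through the same pipeline
  vst_all <- normalize_vst(
    filter_low_counts(sim$counts, sim$annotations$definition))$vst
  corrected_all <- correct_batch(vst_all, sim$annotations$batch,
                                 covariates = data.frame(
                                   definition = sim$annotations$definition))
  genes <- intersect(rownames(vg), rownames(corrected_all))
  repro_pca <- fit_pca(corrected_all[genes, ], 10)
  repro_clin <- repro_pca$scores[!is_cl, ]
  repro_cl <- repro_pca$scores[is_cl, ]

  model <- train_shift_projection(frozen$scores[, 1:10], repro_clin,
                                  n_components = 5, seed = 2)
  mapped <- map_new_samples(model, repro_cl)
  aligned_raw <- tripletrx:::apply_alignment(repro_cl, model$alignment)

  # frozen-space subtype centroids from the clinical samples
  centroids <- sapply(names(sim$truth$subtype[!is_cl]) |>
                        (\(s) split(s, sim$truth$subtype[!is_cl]))(),
                      function(s) colMeans(frozen$scores[s, 1:5, drop = FALSE]))
  truth_cl <- sim$truth$subtype[is_cl]
  dist_to_own <- function(coords) {
    vapply(seq_len(nrow(coords)), function(i)
      sqrt(sum((coords[i, 1:5] - centroids[, truth_cl[i]])^2)), numeric(1))
  }
  improved <- dist_to_own(mapped) < dist_to_own(aligned_raw)
  expect_gte(mean(improved), 0.9)

  # nearest clinical centroid is the line's own subtype for most lines
  nearest <- vapply(seq_len(nrow(mapped)), function(i)
    colnames(centroids)[which.min(colSums((centroids - mapped[i, 1:5])^2))],
    character(1))
  expect_gte(mean(nearest == truth_cl), 8 / 12)
})
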