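#' Discard genes with low counts in the smallest sample group
#'
#' A gene is kept iff its total count in the smallest annotation group (e.g.
#' normal vs. tumor tissue) exceeds `min_count`; gene order is preserved.
#' The operation is idempotent.
#'
#' @param counts Integer matrix, genes x samples.
#' @param groups Vector of group labels, one per sample (a partition of the
#'   columns).
#' @param min_count Threshold; totals `<= min_count` in the smallest group
#'   discard the gene (default 10).
#' @return The filtered count matrix.
#' @export
filter_low_counts <- function(counts, groups, min_count = 10) {
  stopifnot(is.matrix(counts), length(groups) == ncol(counts))
  groups <- as.factor(groups)
  if (any(table(groups) == 0L)) stop("empty sample group")
  smallest <- names(which.min(table(groups)))
  totals <- rowSums(counts[, groups == smallest, drop = FALSE])
  counts[totals > min_count, , drop = FALSE]
}

# median-of-ratios size factors against a geometric-mean pseudo-reference
median_of_ratios <- function(counts) {
  all_pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(all_pos)) {
    message("no gene is nonzero in every sample; using the positive subset ",
            "of each sample for the reference")
    log_ref <- rowMeans(log(counts + 0.5))  # damped fallback reference
    use <- rep(TRUE, nrow(counts))
  } else {
    log_ref <- rowMeans(log(counts[all_pos, , drop = FALSE]))
    use <- all_pos
  }
  sf <- apply(counts[use, , drop = FALSE], 2L, function(cnt) {
    ok <- cnt > 0
    exp(stats::median(log(cnt[ok]) - log_ref[ok]))
  })
  sf
}

#' Normalize counts and apply a variance-stabilizing transform
#'
#' Size factors are median-of-ratios against a geometric-mean pseudo-reference
#' built from genes with nonzero counts in every sample (identical samples get
#' size factor 1; doubling a sample's counts doubles its factor). The
#' variance-stabilizing transform is `log2(count / sizefactor + 1)`, which
#' flattens the count SD-vs-mean trend across the expressed range without the
#' dispersion machinery of model-based VSTs.
#'
#' @param counts Integer matrix, genes x samples.
#' @return List of class `vst_result`: `vst` (transformed matrix),
#'   `size_factors`, `normalized` (counts / size factor).
#' @export
normalize_vst <- function(counts) {
  stopifnot(is.matrix(counts), all(counts >= 0))
  sf <- median_of_ratios(counts)
  norm <- sweep(counts, 2L, sf, "/")
  structure(list(vst = log2(norm + 1), size_factors = sf, normalized = norm),
            class = "vst_result")
}

#' Remove additive batch effects from a normalized expression matrix
#'
#' Fits a per-gene linear model with batch indicators plus any preserved
#' covariates and subtracts the fitted batch terms, leaving covariate effects
#' untouched (delegated to `limma::removeBatchEffect`). A batch structure
#' aliased 1:1 with a preserved covariate is refused, since the batch term
#' would then absorb biology.
#'
#' @param x Numeric matrix (genes x samples), e.g. the `vst` slot of
#'   [normalize_vst()].
#' @param batch Vector of batch labels, one per column.
#' @param covariates Optional data frame of biological covariates to preserve
#'   (one row per sample).
#' @return The corrected matrix; unchanged if only one batch is present.
#' @export
correct_batch <- function(x, batch, covariates = NULL) {
  stopifnot(is.matrix(x), length(batch) == ncol(x))
  batch <- as.factor(batch)
  if (nlevels(batch) < 2L) return(x)
  design <- matrix(1, ncol(x), 1L, dimnames = list(NULL, "(Intercept)"))
  if (!is.null(covariates)) {
    stopifnot(nrow(covariates) == ncol(x))
    design <- stats::model.matrix(~ ., data = as.data.frame(covariates))
    # aliasing check: the combined [covariates | batch] design must have full rank
    full <- cbind(design, stats::model.matrix(~ batch)[, -1, drop = FALSE])
    if (qr(full)$rank < ncol(full)) {
      for (v in names(covariates)) {
        tab <- table(covariates[[v]], batch)
        if (all(rowSums(tab > 0) == 1L))
          stop("batch is confounded with covariate '", v,
               "': batch terms are aliased and cannot be separated")
      }
      stop("batch indicators are aliased with the preserved covariates")
    }
  }
  limma::removeBatchEffect(x, batch = batch, design = design)
}

#' Select the most variable genes
#'
#' Keeps the `n` rows with the largest sample variance; ties break
#' deterministically by gene id (row name). Idempotent.
#'
#' @param x Numeric matrix, genes x samples.
#' @param n Number of genes to retain (default 2500).
#' @return Matrix restricted to the selected genes (original row order of the
#'   variance ranking: most variable first).
#' @export
select_variable_genes <- function(x, n = 2500) {
  stopifnot(is.matrix(x))
  if (n > nrow(x))
    stop("n = ", n, " exceeds the ", nrow(x), " genes available")
  v <- row_vars(x)
  ids <- rownames(x) %||% as.character(seq_len(nrow(x)))
  ord <- order(-v, ids)
  x[ord[seq_len(n)], , drop = FALSE]
}

# within-cluster sum of squares of the best k-means run
best_kmeans <- function(tx, k, n_starts, iter_max = 100) {
  # Lloyd with random starts can transiently empty a cluster; the multi-start
  # wrapper already discards those runs, so the warning carries no information
  withCallingHandlers(
    stats::kmeans(tx, centers = k, nstart = n_starts, iter.max = iter_max,
                  algorithm = "Lloyd"),
    warning = function(w) {
      if (grepl("empty cluster|did not converge", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
}

# gap-statistic reference draws: uniform in the PCA-aligned bounding box
gap_reference_logw <- function(tx, ks, B, n_starts_ref) {
  ctr <- colMeans(tx)
  xc <- sweep(tx, 2L, ctr)
  sv <- svd(xc, nu = 0)
  rot <- xc %*% sv$v
  rng <- apply(rot, 2L, range)
  n <- nrow(tx)
  logw <- matrix(NA_real_, B, length(ks))
  for (b in seq_len(B)) {
    z <- vapply(seq_len(ncol(rot)),
                function(j) stats::runif(n, rng[1, j], rng[2, j]),
                numeric(n))
    ref <- z %*% t(sv$v)
    logw[b, ] <- vapply(ks, function(k) {
      if (k == 1L) log(sum(scale(ref, scale = FALSE)^2))
      else log(best_kmeans(ref, k, n_starts_ref)$tot.withinss)
    }, numeric(1))
  }
  logw
}

#' k-means clustering with cluster-number diagnostics
#'
#' Runs Lloyd k-means (best of `n_starts` random starts by total
#' within-cluster sum of squares) for every k in `k_range` on the samples of
#' an expression matrix, and reports three cluster-number diagnostics: mean
#' silhouette width (Euclidean), the WSS elbow curve, and the gap statistic
#' (uniform reference sampled in the PCA-aligned bounding box of the data,
#' `gap_B` reference draws, scanned from k = 1). The selected k is the
#' silhouette argmax; the gap statistic's one-SE choice and the elbow curve
#' are reported as corroborating diagnostics, not used for selection.
#'
#' @param x Numeric matrix, genes x samples; columns are clustered.
#' @param k_range Integer vector of cluster numbers to scan (default 2:10).
#' @param n_starts Random starts per k (default 25).
#' @param gap_B Reference datasets for the gap statistic (default 50).
#' @param n_starts_ref Random starts per reference k-means run (default 5).
#' @param seed Optional seed making starts and reference draws reproducible.
#' @return Object of class `cluster_solution`: `k` (selected), `assignments`,
#'   `centroids`, `diagnostics` (per-k table with `wss`, `silhouette`, `gap`,
#'   `gap_se`), `gap_k` (one-SE gap choice over k >= 1), `selection_rule`.
#' @export
kmeans_diagnostics <- function(x, k_range = 2:10, n_starts = 25, gap_B = 50,
                               n_starts_ref = 5, seed = NULL) {
  stopifnot(is.matrix(x), all(k_range >= 2L))
  tx <- t(x)
  if (nrow(tx) < max(k_range))
    stop("fewer samples than the largest k scanned")
  if (nrow(unique(tx)) < max(k_range))
    stop("fewer distinct samples than the largest k scanned; clustering is degenerate")

  with_seed(seed, {
    d <- stats::dist(tx)
    fits <- lapply(k_range, function(k) best_kmeans(tx, k, n_starts))
    sil <- vapply(seq_along(k_range), function(i) {
      mean(cluster::silhouette(fits[[i]]$cluster, d)[, "sil_width"])
    }, numeric(1))
    wss <- vapply(fits, `[[`, numeric(1), "tot.withinss")

    gap_ks <- 1:max(k_range)
    obs_logw <- vapply(gap_ks, function(k) {
      if (k == 1L) log(sum(scale(tx, scale = FALSE)^2))
      else if (k %in% k_range) log(wss[match(k, k_range)])
      else log(best_kmeans(tx, k, n_starts)$tot.withinss)
    }, numeric(1))
    ref_logw <- gap_reference_logw(tx, gap_ks, gap_B, n_starts_ref)
    gap <- colMeans(ref_logw) - obs_logw
    gap_se <- apply(ref_logw, 2L, stats::sd) * sqrt(1 + 1 / gap_B)

    # one-SE rule: smallest k with gap(k) >= gap(k+1) - se(k+1)
    gap_k <- max(gap_ks)
    for (i in seq_len(length(gap_ks) - 1L)) {
      if (gap[i] >= gap[i + 1L] - gap_se[i + 1L]) { gap_k <- gap_ks[i]; break }
    }

    best <- which.max(sil)
    diagnostics <- data.frame(k = k_range, wss = wss, silhouette = sil,
                              gap = gap[match(k_range, gap_ks)],
                              gap_se = gap_se[match(k_range, gap_ks)])
    structure(list(k = k_range[best],
                   assignments = fits[[best]]$cluster,
                   centroids = fits[[best]]$centers,
                   diagnostics = diagnostics,
                   gap_full = data.frame(k = gap_ks, gap = gap, se = gap_se),
                   gap_k = gap_k,
                   selection_rule = "silhouette argmax",
                   fits = fits, k_range = k_range),
              class = "cluster_solution")
  })
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat("k-means cluster-number diagnostics (", x$selection_rule, ")\n", sep = "")
  cat("  selected k =", x$k, "| gap one-SE choice: k =", x$gap_k, "\n")
  print(x$diagnostics, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
plot.cluster_solution <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 3)); on.exit(graphics::par(op))
  with(x$diagnostics, {
    plot(k, wss, type = "b", main = "elbow", ylab = "within-cluster SS")
    plot(k, silhouette, type = "b", main = "silhouette", ylab = "mean width")
    graphics::abline(v = x$k, lty = 2)
  })
  with(x$gap_full, {
    plot(k, gap, type = "b", main = "gap", ylim = range(gap - se, gap + se))
    graphics::arrows(k, gap - se, k, gap + se, angle = 90, code = 3, length = 0.03)
    graphics::abline(v = x$gap_k, lty = 2)
  })
  invisible(x)
}

#' Principal-component embedding of samples
#'
#' Centered (not scaled) PCA with samples as observations. Component signs
#' follow a deterministic convention: the loading entry with the largest
#' absolute value is made positive, so repeated fits of the same data give
#' identical embeddings.
#'
#' @param x Numeric matrix, genes x samples.
#' @param n_components Number of components to keep.
#' @return Object of class `pca_model`: `center` (gene means), `rotation`
#'   (genes x components, orthonormal), `scores` (samples x components),
#'   `explained_var` (fractions, non-increasing), `sdev`.
#' @export
fit_pca <- function(x, n_components) {
  stopifnot(is.matrix(x))
  max_nc <- min(nrow(x), ncol(x) - 1L)
  if (n_components > max_nc)
    stop("n_components exceeds min(genes, samples - 1) = ", max_nc)
  pc <- stats::prcomp(t(x), center = TRUE, scale. = FALSE)
  rot <- pc$rotation[, seq_len(n_components), drop = FALSE]
  flip <- vapply(seq_len(ncol(rot)),
                 function(j) sign(rot[which.max(abs(rot[, j])), j]),
                 numeric(1))
  rot <- sweep(rot, 2L, flip, "*")
  scores <- sweep(pc$x[, seq_len(n_components), drop = FALSE], 2L, flip, "*")
  structure(list(center = pc$center, rotation = rot, scores = scores,
                 sdev = pc$sdev[seq_len(n_components)],
                 explained_var = pc$sdev[seq_len(n_components)]^2 /
                   sum(pc$sdev^2),
                 n_components = n_components),
            class = "pca_model")
}

#' Project samples into a fitted PCA space
#'
#' @param model A [fit_pca()] model.
#' @param x Numeric matrix, genes x samples, with the same genes (rows) the
#'   model was fitted on.
#' @return Coordinate matrix, samples x components.
#' @export
apply_pca <- function(model, x) {
  stopifnot(inherits(model, "pca_model"), is.matrix(x))
  if (nrow(x) != length(model$center))
    stop("gene dimension mismatch: model has ", length(model$center),
         " genes, input has ", nrow(x))
  sweep(t(x), 2L, model$center) %*% model$rotation
}

#' @export
print.pca_model <- function(x, ...) {
  cat("PCA model:", length(x$center), "genes,", x$n_components, "components\n")
  cat("  explained variance:",
      paste(sprintf("%.1f%%", 100 * x$explained_var), collapse = ", "), "\n")
  invisible(x)
}

# greedy alignment of reprocessed PCs to original PCs by maximal |correlation|;
# the match must be unambiguous (|r| >= min_abs_cor) for the first n_strict
# components (the ones whose shift is corrected) — higher, noise-dominated
# components are aligned best-effort
align_components <- function(original, reprocessed, n_strict,
                             n_total = n_strict, min_abs_cor = 0.3) {
  n_align <- min(ncol(original), n_total)
  perm <- integer(n_align); signs <- numeric(n_align)
  avail <- rep(TRUE, ncol(reprocessed))
  for (j in seq_len(n_align)) {
    r <- vapply(seq_len(ncol(reprocessed)), function(m)
      if (avail[m]) stats::cor(original[, j], reprocessed[, m]) else 0,
      numeric(1))
    m <- which.max(abs(r))
    if (j <= n_strict && abs(r[m]) < min_abs_cor)
      stop("component ", j, " could not be matched (max |r| = ",
           format(abs(r[m]), digits = 2),
           " < ", min_abs_cor, "); embeddings are not comparable")
    perm[j] <- m; signs[j] <- if (r[m] < 0) -1 else 1; avail[m] <- FALSE
  }
  # remaining columns pass through in their original order
  rest <- which(avail)
  list(perm = c(perm, rest), signs = c(signs, rep(1, length(rest))),
       n_matched = n_align)
}

apply_alignment <- function(coords, alignment) {
  out <- coords[, alignment$perm, drop = FALSE]
  sweep(out, 2L, alignment$signs, "*")
}

#' Train per-component elastic-net shift regressors between two embeddings
#'
#' When a frozen PCA space is re-derived after adding new samples
#' (integrated reprocessing), the coordinates of the shared samples shift
#' slightly. This fits, for each of the first `n_components` components, an
#' elastic-net regression (mixing parameter 0.5, penalty by 5-fold
#' cross-validation) predicting the shift `original - reprocessed` from the
#' reprocessed top-`n_predictors` coordinates. Before training, reprocessed
#' components are aligned to the original ones (order and sign) by maximal
#' absolute correlation; an ambiguous match (|r| < 0.3) is an error.
#'
#' @param original Coordinates of the shared samples in the frozen embedding
#'   (samples x components).
#' @param reprocessed Coordinates of the same samples (same row order) from
#'   the integrated reprocessing run.
#' @param n_components Number of components to correct (default 5).
#' @param n_predictors Number of (aligned) reprocessed coordinates used as
#'   predictors (default 10, capped at the available columns).
#' @param seed Seed for the cross-validation folds.
#' @return Object of class `projection_model` with per-component intercepts
#'   and coefficient vectors, the component alignment, and per-component CV
#'   error.
#' @export
train_shift_projection <- function(original, reprocessed, n_components = 5,
                                   n_predictors = 10, seed = 1) {
  stopifnot(is.matrix(original), is.matrix(reprocessed),
            nrow(original) == nrow(reprocessed))
  if (!is.null(rownames(original)) && !is.null(rownames(reprocessed)) &&
      !identical(rownames(original), rownames(reprocessed)))
    stop("original and reprocessed coordinates must cover the same samples ",
         "in the same order")
  n_components <- min(n_components, ncol(original))
  n_predictors <- min(n_predictors, ncol(reprocessed))
  alignment <- align_components(original, reprocessed, n_strict = n_components,
                                n_total = max(n_components, n_predictors))
  rp <- apply_alignment(reprocessed, alignment)
  X <- rp[, seq_len(n_predictors), drop = FALSE]

  models <- with_seed(seed, lapply(seq_len(n_components), function(j) {
    y <- original[, j] - rp[, j]
    if (stats::sd(y) < 1e-12)
      return(list(intercept = mean(y),
                  beta = numeric(ncol(X)), cv_error = 0))
    cv <- glmnet::cv.glmnet(X, y, alpha = 0.5, nfolds = 5)
    cf <- as.numeric(stats::coef(cv, s = "lambda.min"))
    list(intercept = cf[1L], beta = cf[-1L],
         cv_error = min(cv$cvm))
  }))

  structure(list(models = models, alignment = alignment,
                 n_components = n_components, n_predictors = n_predictors,
                 cv_error = vapply(models, `[[`, numeric(1), "cv_error")),
            class = "projection_model")
}

#' @export
print.projection_model <- function(x, ...) {
  cat("Elastic-net shift projection:", x$n_components,
      "corrected components,", x$n_predictors, "predictors\n")
  cat("  CV error per component:",
      paste(sprintf("%.3g", x$cv_error), collapse = ", "), "\n")
  invisible(x)
}

#' Map new samples into the frozen embedding
#'
#' Applies the trained component alignment to the new samples' reprocessed
#' coordinates and adds the predicted shift on each corrected component;
#' components beyond the corrected set pass through unchanged.
#'
#' @param model A [train_shift_projection()] model.
#' @param coords New-sample coordinates from the same integrated reprocessing
#'   run (samples x components; at least `n_predictors` columns).
#' @return Corrected coordinates, samples x components, in the frozen
#'   embedding's orientation.
#' @export
map_new_samples <- function(model, coords) {
  stopifnot(inherits(model, "projection_model"), is.matrix(coords))
  if (ncol(coords) < max(model$n_predictors, model$n_components) ||
      ncol(coords) < length(model$alignment$perm))
    stop("coordinate dimension mismatch: model expects at least ",
         length(model$alignment$perm), " components, got ", ncol(coords))
  al <- apply_alignment(coords, model$alignment)
  X <- al[, seq_len(model$n_predictors), drop = FALSE]
  out <- al
  for (j in seq_len(model$n_components)) {
    m <- model$models[[j]]
    out[, j] <- al[, j] + m$intercept + as.numeric(X %*% m$beta)
  }
  out
}

#' @export
predict.projection_model <- function(object, newdata, ...) {
  map_new_samples(object, newdata)
}
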