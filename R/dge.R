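#' Benjamini-Hochberg step-up adjustment
#'
#' Validating wrapper around `stats::p.adjust(method = "BH")`: monotone in p,
#' capped at 1, errors on p-values outside \[0, 1\].
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values.
#' @export
benjamini_hochberg <- function(p) {
  if (!is.numeric(p) || any(!is.na(p) & (p < 0 | p > 1)))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

# method-of-moments NB dispersion from normalized counts, pooled over groups
mom_dispersion <- function(q, grp, floor = 1e-8) {
  est <- vapply(levels(grp), function(g) {
    qq <- q[grp == g]
    m <- mean(qq)
    if (m <= 0) return(c(0, 0))
    c((stats::var(qq) - m) / m^2 * (length(qq) - 1L), length(qq) - 1L)
  }, numeric(2))
  w <- est[2L, ]
  if (sum(w) == 0) return(floor)
  max(sum(est[1L, ]) / sum(w), floor)
}

#' Negative-binomial Wald differential expression
#'
#' Per-gene NB generalized linear model `count ~ group` with log size-factor
#' offsets, a method-of-moments dispersion estimate pooled across the two
#' groups (floored at 1e-8), and a Wald test on the group coefficient,
#' followed by Benjamini-Hochberg correction across tested genes. Genes are
#' flagged as differentially expressed at `padj < alpha` and
#' `|log2FC| > lfc_threshold`. Dispersion is estimated per gene without
#' empirical-Bayes shrinkage; the calibration consequences are covered by the
#' test suite.
#'
#' @param counts Integer matrix, genes x samples (filtered upstream).
#' @param labels Group label per sample; exactly two distinct labels.
#' @param reference The reference (denominator) label.
#' @param size_factors Optional sample size factors; default median-of-ratios
#'   computed from `counts`.
#' @param alpha Adjusted-p threshold for the DEG flag (default 0.05).
#' @param lfc_threshold |log2FC| threshold for the DEG flag (default 1).
#' @return Data frame of class `de_result`: `gene`, `base_mean`, `log2fc`,
#'   `se`, `stat` (Wald z), `pvalue`, `padj`, `deg`.
#' @export
differential_expression <- function(counts, labels, reference,
                                    size_factors = NULL,
                                    alpha = 0.05, lfc_threshold = 1) {
  stopifnot(is.matrix(counts), length(labels) == ncol(counts))
  labels <- as.character(labels)
  lv <- unique(labels)
  if (length(lv) != 2L) stop("exactly two groups are required; got ", length(lv))
  if (!reference %in% lv) stop("reference label '", reference, "' not present")
  if (any(table(labels) < 2L)) stop("both groups need at least 2 samples")
  grp <- stats::relevel(factor(labels), ref = reference)
  if (all(row_vars(counts) == 0)) stop("all genes have zero variance")
  sf <- size_factors %||% median_of_ratios(counts)
  off <- log(sf)
  q <- sweep(counts, 2L, sf, "/")

  n <- nrow(counts)
  res <- matrix(NA_real_, n, 4L,
                dimnames = list(rownames(counts), c("log2fc", "se", "stat", "pvalue")))
  for (i in seq_len(n)) {
    y <- counts[i, ]
    if (sum(y) == 0) next
    disp <- mom_dispersion(q[i, ], grp)
    fit <- tryCatch(
      suppressWarnings(stats::glm(y ~ grp + offset(off),
                                  family = MASS::negative.binomial(1 / disp))),
      error = function(e) NULL)
    if (is.null(fit)) next
    sm <- summary(fit)$coefficients
    if (nrow(sm) < 2L) next
    beta <- sm[2L, 1L]; se <- sm[2L, 2L]
    z <- beta / se
    res[i, ] <- c(beta / log(2), se / log(2), z, 2 * stats::pnorm(-abs(z)))
  }

  padj <- rep(NA_real_, n)
  tested <- !is.na(res[, "pvalue"])
  padj[tested] <- benjamini_hochberg(res[tested, "pvalue"])
  out <- data.frame(gene = rownames(counts) %||% as.character(seq_len(n)),
                    base_mean = rowMeans(q),
                    log2fc = res[, "log2fc"], se = res[, "se"],
                    stat = res[, "stat"], pvalue = res[, "pvalue"],
                    padj = padj,
                    deg = !is.na(padj) & padj < alpha &
                      abs(res[, "log2fc"]) > lfc_threshold,
                    row.names = NULL)
  class(out) <- c("de_result", "data.frame")
  out
}

# weighted Kolmogorov-Smirnov running-sum enrichment score from sorted hit
# positions; weights are |stat| of the ranked list
gsea_es <- function(hit_pos, weights, N) {
  h <- length(hit_pos)
  hit_pos <- sort(hit_pos)
  w <- weights[hit_pos]
  sw <- sum(w)
  if (sw == 0) w <- rep(1 / h, h) else w <- w / sw
  hit_cum <- cumsum(w)
  miss_after <- (hit_pos - seq_len(h)) / (N - h)   # misses strictly before each hit
  dev_at_hit <- hit_cum - miss_after               # running sum just after each hit
  dev_before <- c(0, hit_cum[-h]) - miss_after     # just before each hit
  cand <- c(dev_at_hit, dev_before)
  cand[which.max(abs(cand))]
}

#' Preranked gene-set enrichment with a gene-permutation null
#'
#' Computes the weighted Kolmogorov-Smirnov enrichment score (hit increments
#' proportional to |statistic|, maximum-deviation convention) for each gene
#' set against a ranking of genes by a signed statistic (e.g. the Wald
#' statistic of [differential_expression()]). The null distribution comes
#' from `n_perm` gene-label permutations (equivalently, random sets of the
#' same size); NES is ES divided by the mean |null ES| of matching sign and
#' the permutation p-value is one-sided within the matching-sign null
#' (doubled-tail convention via sign matching), BH-corrected across sets.
#'
#' @param stats_ranked Named numeric vector of per-gene statistics (finite,
#'   unique names); larger = more up-regulated.
#' @param sets Named list of gene-id vectors (e.g. from [read_gmt()]).
#' @param n_perm Number of permutations (default 10000).
#' @param min_size,max_size Set-size bounds after intersecting with the
#'   ranking (defaults 15 and 500); sets outside the bounds are excluded.
#' @param seed Optional seed.
#' @return Data frame of class `enrichment_result`: `pathway`, `size`, `es`,
#'   `nes`, `pval`, `padj`, ordered as given. Sets with no member in the
#'   ranking are dropped with a warning.
#' @export
gsea_preranked <- function(stats_ranked, sets, n_perm = 10000,
                           min_size = 15, max_size = 500, seed = NULL) {
  stopifnot(is.numeric(stats_ranked), !is.null(names(stats_ranked)),
            all(is.finite(stats_ranked)))
  if (anyDuplicated(names(stats_ranked))) stop("gene ids must be unique")
  ord <- order(stats_ranked, decreasing = TRUE)
  ranked_genes <- names(stats_ranked)[ord]
  weights <- abs(stats_ranked[ord])
  N <- length(ranked_genes)

  absent <- names(sets)[vapply(sets, function(s)
    !any(s %in% ranked_genes), logical(1))]
  if (length(absent))
    warning("set(s) entirely absent from the ranking dropped: ",
            paste(absent, collapse = ", "))
  pos <- lapply(sets, function(s) which(ranked_genes %in% unique(s)))
  sizes <- lengths(pos)
  keep <- sizes >= min_size & sizes <= max_size
  pos <- pos[keep]; sizes <- sizes[keep]
  if (length(pos) == 0L)
    return(structure(data.frame(pathway = character(0), size = integer(0),
                                es = numeric(0), nes = numeric(0),
                                pval = numeric(0), padj = numeric(0)),
                     class = c("enrichment_result", "data.frame")))

  es <- vapply(pos, gsea_es, numeric(1), weights = weights, N = N)

  # null ES depends on the ranking and the set size only: cache per size
  null_by_size <- with_seed(seed, {
    out <- list()
    for (h in sort(unique(sizes))) {
      out[[as.character(h)]] <- vapply(seq_len(n_perm), function(b)
        gsea_es(sample.int(N, h), weights, N), numeric(1))
    }
    out
  })

  nes <- pval <- numeric(length(es))
  for (i in seq_along(es)) {
    null <- null_by_size[[as.character(sizes[i])]]
    same <- null[sign(null) == sign(es[i])]
    denom <- mean(abs(same))
    nes[i] <- if (length(same) && denom > 0) es[i] / denom else NA_real_
    pval[i] <- (1 + sum(abs(same) >= abs(es[i]))) / (1 + length(same))
  }
  out <- data.frame(pathway = names(pos), size = as.integer(sizes),
                    es = unname(es), nes = nes, pval = pval,
                    padj = benjamini_hochberg(pval), row.names = NULL)
  attr(out, "n_perm") <- n_perm
  class(out) <- c("enrichment_result", "data.frame")
  out
}
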