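#' Bliss-independence expected inhibition
#'
#' Under Bliss independence, drugs act as independent probabilistic events:
#' the expected combined fractional inhibition of single agents with effects
#' \eqn{e_1, \ldots, e_n} is \eqn{E = 1 - \prod_i (1 - e_i)}. Values outside
#' \[0, 1\] (stimulation artifacts, super-maximal readouts) are clamped with a
#' warning before composing.
#'
#' @param e Numeric vector of single-agent fractional inhibitions.
#' @return Expected combined fractional inhibition (scalar).
#' @examples
#' bliss_expected(c(0.2, 0.3))       # 0.44
#' bliss_expected(c(0.2, 0.3, 0.5))  # 0.72
#' @export
bliss_expected <- function(e) {
  stopifnot(is.numeric(e), length(e) >= 1L)
  if (any(e < 0 | e > 1)) {
    warning("fractional inhibitions outside [0, 1] clamped for Bliss expectation")
    e <- pmin(pmax(e, 0), 1)
  }
  1 - prod(1 - e)
}

# locate the dose columns of a surface data frame
surface_dose_cols <- function(surface, response_col) {
  cols <- setdiff(names(surface), c(response_col, "replicate"))
  if (length(cols) < 2L || length(cols) > 3L)
    stop("surface must have 2 or 3 dose columns besides '", response_col, "'")
  cols
}

# per-drug single-agent margins: named list of dose -> fractional inhibition,
# clamped to [0,1] for expectation composition
surface_margins <- function(cells, drugs) {
  doses <- as.matrix(cells[, drugs, drop = FALSE])
  margins <- list()
  for (i in seq_along(drugs)) {
    d_i <- sort(unique(doses[doses[, i] > 0, i]))
    single <- doses[, i] > 0 & rowSums(doses[, -i, drop = FALSE] > 0) == 0L
    vals <- stats::setNames(cells$observed[single], doses[single, i])
    missing <- setdiff(as.character(d_i), names(vals))
    if (length(missing))
      stop("missing single-agent margin for ", drugs[i], " at dose ",
           paste(missing, collapse = ", "))
    margins[[drugs[i]]] <- pmin(pmax(vals / 100, 0), 1)
  }
  margins
}

# collapse replicate rows to cell means; observed on the % inhibition scale
surface_cells <- function(surface, drugs, response_col, viability) {
  resp <- surface[[response_col]]
  if (viability) resp <- 100 * (1 - resp)
  key <- do.call(paste, c(surface[drugs], sep = "\r"))
  agg <- rowsum(resp, key)
  cnt <- table(key)
  agg <- agg / as.vector(cnt[rownames(agg)])
  # rowsum orders cells by key; rebuild the dose columns from the key
  keys <- rownames(agg)
  dose_mat <- do.call(rbind, lapply(strsplit(keys, "\r", fixed = TRUE), as.numeric))
  cells <- data.frame(dose_mat, observed = as.numeric(agg))
  names(cells)[seq_along(drugs)] <- drugs
  cells
}

score_cells <- function(cells, margins, drugs, combo_mask) {
  doses <- as.matrix(cells[, drugs, drop = FALSE])
  expected <- vapply(which(combo_mask), function(r) {
    e <- vapply(seq_along(drugs), function(i) {
      if (doses[r, i] > 0) margins[[drugs[i]]][[as.character(doses[r, i])]] else 0
    }, numeric(1))
    bliss_expected(e)
  }, numeric(1))
  excess <- cells$observed[combo_mask] - 100 * expected
  grid <- cells[combo_mask, , drop = FALSE]
  grid$expected_pct <- 100 * expected
  grid$excess <- excess
  rownames(grid) <- NULL
  grid
}

classify_score <- function(score) {
  if (score < -10) "antagonistic" else if (score > 10) "synergistic" else "additive"
}

#' Overall Bliss synergy score of a factorial dose-response surface
#'
#' For every combination cell (two or more nonzero doses) the Bliss excess is
#' the observed percent inhibition minus 100 times the Bliss expectation
#' composed from that cell's single-agent margins. The overall score is the
#' unweighted mean excess over combination cells, in percentage points;
#' scores below -10 are classified antagonistic, above +10 synergistic, and
#' in between additive. Margins are clamped to \[0, 1\] for the expectation
#' but observed values enter the excess unclamped.
#'
#' @param surface Data frame with one dose column per drug (2 or 3 drugs,
#'   dose 0 rows included for the single-agent margins), an optional
#'   `replicate` column, and a response column. Replicate rows for the same
#'   dose combination are averaged.
#' @param response_col Name of the response column.
#' @param viability If `TRUE` the response is relative viability `v` (vehicle
#'   = 1) and is converted to percent inhibition `100 (1 - v)`; if `FALSE`
#'   (default) the response is already percent inhibition (0-100).
#' @param n_boot If > 0 and a `replicate` column is present, number of
#'   bootstrap resamples of replicate wells for a percentile CI of the score.
#' @param conf Bootstrap confidence level.
#' @param seed Optional seed for the bootstrap.
#' @return Object of class `synergy_result`: `score`, `classification`,
#'   `excess` (per-cell grid with observed, expected and excess), `n_cells`,
#'   optional `ci`.
#' @examples
#' surf <- data.frame(a = c(0, 1, 0, 1), b = c(0, 0, 1, 1),
#'                    inhibition_pct = c(0, 20, 30, 50))
#' bliss_synergy_score(surf)$score  # 6
#' @export
bliss_synergy_score <- function(surface, response_col = "inhibition_pct",
                                viability = FALSE, n_boot = 0, conf = 0.95,
                                seed = NULL) {
  stopifnot(is.data.frame(surface), response_col %in% names(surface))
  drugs <- surface_dose_cols(surface, response_col)
  cells <- surface_cells(surface, drugs, response_col, viability)
  margins <- surface_margins(cells, drugs)
  combo <- rowSums(as.matrix(cells[, drugs, drop = FALSE]) > 0) >= 2L
  if (!any(combo)) stop("surface has no combination cells")
  grid <- score_cells(cells, margins, drugs, combo)
  score <- mean(grid$excess)

  ci <- NULL
  if (n_boot > 0 && "replicate" %in% names(surface)) {
    key <- do.call(paste, c(surface[drugs], sep = "\r"))
    boots <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
      idx <- unlist(lapply(split(seq_len(nrow(surface)), key), function(ii)
        ii[sample.int(length(ii), replace = TRUE)]), use.names = FALSE)
      sb <- surface[idx, ]
      cb <- surface_cells(sb, drugs, response_col, viability)
      mb <- surface_margins(cb, drugs)
      mean(score_cells(cb, mb, drugs,
                       rowSums(as.matrix(cb[, drugs, drop = FALSE]) > 0) >= 2L)$excess)
    }, numeric(1)))
    a <- (1 - conf) / 2
    ci <- stats::quantile(boots, c(a, 1 - a), names = FALSE)
  }

  structure(list(score = score, classification = classify_score(score),
                 excess = grid, n_cells = sum(combo), drugs = drugs,
                 ci = ci, conf = conf),
            class = "synergy_result")
}

#' @export
print.synergy_result <- function(x, ...) {
  cat(sprintf("Bliss synergy score: %.2f (%s) over %d combination cells [%s]\n",
              x$score, x$classification, x$n_cells,
              paste(x$drugs, collapse = " x ")))
  if (!is.null(x$ci))
    cat(sprintf("  %d%% bootstrap CI: [%.2f, %.2f]\n", round(100 * x$conf),
                x$ci[1], x$ci[2]))
  invisible(x)
}

#' Build a percent-inhibition surface from a two-timepoint viability table
#'
#' Computes, per condition, the endpoint signal fold change relative to its
#' own baseline, normalizes it to the vehicle control (relative viability,
#' vehicle = 1), and converts to percent inhibition `100 (1 - v)`. The
#' zero-dose corner is exactly 0 by construction, which is the normalization
#' [bliss_synergy_score()] expects.
#'
#' @param table A `viability_table` (see [simulate_viability_timecourse()]).
#' @return Data frame with the dose columns and `inhibition_pct`, one row per
#'   condition, ready for [bliss_synergy_score()].
#' @export
viability_surface <- function(table) {
  need <- c("condition", "time_h", "signal", "is_control")
  stopifnot(all(need %in% names(table)))
  t0 <- min(table$time_h); t1 <- max(table$time_h)
  if (!any(table$is_control)) stop("no vehicle control condition in the table")
  x0 <- tapply(table$signal[table$time_h == t0], table$condition[table$time_h == t0], mean)
  x1 <- tapply(table$signal[table$time_h == t1], table$condition[table$time_h == t1], mean)
  fold <- x1 / x0
  ctrl <- unique(table$condition[table$is_control])
  v <- fold / mean(fold[ctrl])
  dose_cols <- setdiff(names(table),
                       c("condition", "replicate", "time_h", "signal", "is_control"))
  first <- table[!duplicated(table$condition), c("condition", dose_cols), drop = FALSE]
  out <- data.frame(first[dose_cols],
                    inhibition_pct = 100 * (1 - as.numeric(v[first$condition])),
                    row.names = NULL, check.names = FALSE)
  out
}

#' Bliss scores of 2-drug slices through a 3-drug surface
#'
#' Scores each two-drug sub-surface of a three-drug factorial surface at a
#' fixed dose of the third drug. At fixed dose 0 this reduces exactly to the
#' two-drug score of the remaining drugs; at a positive fixed dose every cell
#' with at least two active drugs (counting the fixed one) contributes, with
#' the Bliss expectation composed from all three single-agent margins of the
#' full surface.
#'
#' @param surface 3-drug surface as in [bliss_synergy_score()].
#' @param fixed_drug Name of the dose column held fixed.
#' @param fixed_doses Doses of `fixed_drug` to slice at (default: every dose
#'   on its axis). Doses not on the axis are an error.
#' @inheritParams bliss_synergy_score
#' @return Data frame with one row per slice: `fixed_dose`, `score`,
#'   `classification`, `n_cells`; per-slice `synergy_result` objects in the
#'   `slices` attribute.
#' @export
conditional_slice_scores <- function(surface, fixed_drug, fixed_doses = NULL,
                                     response_col = "inhibition_pct",
                                     viability = FALSE) {
  drugs <- surface_dose_cols(surface, response_col)
  if (length(drugs) != 3L) stop("conditional slices need a 3-drug surface")
  if (!fixed_drug %in% drugs) stop("'", fixed_drug, "' is not a dose column")
  axis <- sort(unique(surface[[fixed_drug]]))
  if (is.null(fixed_doses)) fixed_doses <- axis
  off <- setdiff(fixed_doses, axis)
  if (length(off))
    stop("dose(s) not on the ", fixed_drug, " axis: ", paste(off, collapse = ", "))

  cells <- surface_cells(surface, drugs, response_col, viability)
  margins <- surface_margins(cells, drugs)
  free <- setdiff(drugs, fixed_drug)

  slices <- lapply(fixed_doses, function(f) {
    sl <- cells[cells[[fixed_drug]] == f, , drop = FALSE]
    active <- rowSums(as.matrix(sl[, drugs, drop = FALSE]) > 0) >= 2L
    if (!any(active))
      return(structure(list(score = NA_real_, classification = NA_character_,
                            excess = sl[0, ], n_cells = 0L, drugs = drugs,
                            ci = NULL), class = "synergy_result"))
    grid <- score_cells(sl, margins, drugs, active)
    score <- mean(grid$excess)
    structure(list(score = score, classification = classify_score(score),
                   excess = grid, n_cells = sum(active), drugs = drugs,
                   ci = NULL),
              class = "synergy_result")
  })
  out <- data.frame(fixed_dose = fixed_doses,
                    score = vapply(slices, `[[`, numeric(1), "score"),
                    classification = vapply(slices, `[[`, character(1),
                                            "classification"),
                    n_cells = vapply(slices, `[[`, integer(1), "n_cells"))
  attr(out, "slices") <- slices
  attr(out, "fixed_drug") <- fixed_drug
  out
}
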