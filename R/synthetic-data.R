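#' Hill-type drug-effect model for the viability simulator
#'
#' Describes how one or more drugs reduce the net exponential growth rate of a
#' cell population. Each drug has a Hill dose-effect curve
#' \eqn{e(c) = E_{max} c^h / (EC_{50}^h + c^h)} giving the fractional
#' inhibition of growth at concentration \eqn{c}, and a `floor` giving the net
#' growth-rate multiplier at full effect (`floor < 0` means the drug is
#' cytotoxic at saturation: treated populations shrink). The single-drug
#' growth-rate multiplier is \eqn{m_i(c) = 1 - e_i(c)(1 - floor_i)}.
#'
#' Combinations are composed at the viability level: the combined relative
#' viability is the product of the single-agent relative viabilities raised to
#' the interaction exponent `tau` (equivalently, growth-rate deficits are
#' additive and scaled by `tau` when two or more drugs are active).
#' `tau = 1` produces a surface that is exactly consistent with Bliss
#' independence; `tau > 1` plants synergy, `tau < 1` antagonism.
#'
#' @param drugs Named list; each element a list with fields `ec50` (> 0,
#'   concentration units), `hill` (> 0), `emax` (in \[0, 1\]) and optional
#'   `floor` (default 0; may be negative for cytotoxic drugs).
#' @param tau Positive interaction exponent; 1 = Bliss-consistent.
#' @return An object of class `drug_effect_model`.
#' @examples
#' m <- drug_effect_model(list(geda = list(ec50 = 4, hill = 1, emax = 0.9)))
#' @export
drug_effect_model <- function(drugs, tau = 1) {
  stopifnot(is.list(drugs), length(drugs) >= 1L)
  if (is.null(names(drugs)) || anyDuplicated(names(drugs)) || any(names(drugs) == ""))
    stop("'drugs' must be a uniquely named list")
  drugs <- lapply(drugs, function(d) {
    stop_if_not_scalar_pos(d$ec50, "ec50")
    stop_if_not_scalar_pos(d$hill, "hill")
    if (!is.numeric(d$emax) || d$emax < 0 || d$emax > 1)
      stop("'emax' must lie in [0, 1]")
    d$floor <- d$floor %||% 0
    stopifnot(is.numeric(d$floor), length(d$floor) == 1L, is.finite(d$floor))
    d
  })
  stop_if_not_scalar_pos(tau, "tau")
  structure(list(drugs = drugs, tau = tau), class = "drug_effect_model")
}

#' @export
print.drug_effect_model <- function(x, ...) {
  cat("Hill drug-effect model (", length(x$drugs), " drug(s), tau = ",
      x$tau, ")\n", sep = "")
  for (nm in names(x$drugs)) {
    d <- x$drugs[[nm]]
    cat(sprintf("  %-12s EC50 = %g, hill = %g, Emax = %g, floor = %g\n",
                nm, d$ec50, d$hill, d$emax, d$floor))
  }
  invisible(x)
}

hill_effect <- function(drug, dose) {
  ifelse(dose > 0, drug$emax * dose^drug$hill / (drug$ec50^drug$hill + dose^drug$hill), 0)
}

# net growth-rate multiplier for one dose combination (named numeric vector)
growth_multiplier <- function(model, doses) {
  stopifnot(all(names(doses) %in% names(model$drugs)))
  deficits <- vapply(names(doses), function(nm) {
    d <- model$drugs[[nm]]
    hill_effect(d, doses[[nm]]) * (1 - d$floor)
  }, numeric(1))
  n_active <- sum(doses > 0)
  scale <- if (n_active >= 2L) model$tau else 1
  1 - scale * sum(deficits)
}

#' Simulate a two-timepoint viability plate under a drug-effect model
#'
#' Cell populations grow exponentially, \eqn{x(t) = x_0 \cdot 2^{k t}}, with
#' the control growth rate `k0` scaled per condition by the Hill model in
#' `model` (see [drug_effect_model()] for the combination rule). The simulated
#' luminescence signal is proportional to cell number, with multiplicative
#' lognormal measurement noise of coefficient of variation `noise_cv` applied
#' independently to every well at both timepoints.
#'
#' @param design Data frame with one dose column (nM) per drug in `model`
#'   (same names); one row per condition. Must contain at least one all-zero
#'   row, the vehicle control — the GR framework is undefined without it.
#' @param model A [drug_effect_model()].
#' @param k0 Control growth rate, doublings per hour.
#' @param duration Treatment window in hours.
#' @param x0 Baseline signal per well at time 0.
#' @param noise_cv Measurement noise CV (0 = noiseless).
#' @param n_replicates Replicate wells per condition.
#' @param seed Optional integer; seeded runs are bit-identical.
#' @return Long-format data frame of class `viability_table` with columns
#'   `condition`, `replicate`, the dose columns, `time_h`, `signal`,
#'   `is_control`.
#' @examples
#' m <- drug_effect_model(list(geda = list(ec50 = 4, hill = 2, emax = 1)))
#' tab <- simulate_viability_timecourse(data.frame(geda = c(0, 4)), m, seed = 1)
#' @export
simulate_viability_timecourse <- function(design, model, k0 = 1 / 33,
                                          duration = 72, x0 = 1000,
                                          noise_cv = 0, n_replicates = 3,
                                          seed = NULL) {
  stopifnot(inherits(model, "drug_effect_model"), is.data.frame(design))
  drug_names <- names(model$drugs)
  if (!all(drug_names %in% names(design)))
    stop("design must have one dose column per model drug: ",
         paste(setdiff(drug_names, names(design)), collapse = ", "))
  doses <- as.matrix(design[, drug_names, drop = FALSE])
  if (any(doses < 0)) stop("doses must be >= 0")
  stop_if_not_scalar_pos(duration, "duration")
  stop_if_not_scalar_pos(x0, "x0")
  is_ctrl <- rowSums(doses > 0) == 0L
  if (!any(is_ctrl))
    stop("design has no zero-dose control condition; GR is undefined without k(0)")

  k <- k0 * apply(doses, 1L, function(d) growth_multiplier(model, d))
  cond <- sprintf("c%02d", seq_len(nrow(design)))
  out <- with_seed(seed, {
    rows <- expand.grid(replicate = seq_len(n_replicates),
                        i = seq_len(nrow(design)), KEEP.OUT.ATTRS = FALSE)
    n <- nrow(rows)
    noise0 <- lognormal_noise(n, noise_cv)
    noise1 <- lognormal_noise(n, noise_cv)
    data.frame(
      condition = rep(cond[rows$i], 2L),
      replicate = rep(rows$replicate, 2L),
      doses[c(rows$i, rows$i), , drop = FALSE],
      time_h = rep(c(0, duration), each = n),
      signal = c(x0 * noise0, x0 * 2^(k[rows$i] * duration) * noise1),
      is_control = rep(is_ctrl[rows$i], 2L),
      row.names = NULL, check.names = FALSE
    )
  })
  attr(out, "k0") <- k0
  attr(out, "true_k") <- stats::setNames(k, cond)
  class(out) <- c("viability_table", "data.frame")
  out
}

#' Configuration for the synthetic expression cohort
#'
#' Defaults emulate a breast-cancer cohort with five latent transcriptomic
#' states: one normal-like group (A) and four tumor subtype groups (B-E), each
#' tumor group carrying a disjoint block of upregulated signature genes, on
#' top of negative-binomial counts with sample-level library-size factors and
#' a two-batch additive (log2) batch effect. Optional cell-line samples take a
#' subtype profile plus a systematic cell-line shift on a subset of genes,
#' emulating the displacement of cell-line transcriptomes relative to tissue.
#'
#' @param n_genes Number of genes.
#' @param group_sizes Named integer vector of samples per latent subtype
#'   (all >= 2). The first group is treated as normal-like tissue.
#' @param n_marker_genes Signature genes per tumor subtype (disjoint blocks).
#' @param n_shared_tumor_genes Genes of a shared tumor program (cell-cycle /
#'   proliferation-like) upregulated in every tumor subtype, separating the
#'   normal-like group from all tumors (disjoint from the subtype blocks).
#' @param marker_lfc True log2 shift of signature genes in their subtype
#'   (also used for the shared tumor program).
#' @param dispersion NB dispersion (1/size), > 0.
#' @param n_batches Number of technical batches (>= 1).
#' @param batch_sd SD (log2 units) of per-gene batch offsets for non-reference
#'   batches.
#' @param lib_size_range Range of uniform library-size factors.
#' @param base_log2_mean,base_log2_sd Distribution of baseline log2 mean counts.
#' @param n_cell_lines Number of cell-line samples appended to the cohort.
#' @param cell_line_subtypes Subtype labels the cell lines are drawn from
#'   (default the two luminal-like groups).
#' @param cell_line_shift Log2 offset applied to cell-line samples on
#'   `cell_line_shift_frac` of genes.
#' @param cell_line_shift_frac Fraction of genes carrying the cell-line shift.
#' @param seed Integer seed.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_genes = 10000,
                          group_sizes = c(A = 20, B = 45, C = 45, D = 45, E = 45),
                          n_marker_genes = 400,
                          n_shared_tumor_genes = 400,
                          marker_lfc = 2,
                          dispersion = 0.05,
                          n_batches = 2,
                          batch_sd = 0.3,
                          lib_size_range = c(0.6, 1.6),
                          base_log2_mean = 5,
                          base_log2_sd = 2,
                          n_cell_lines = 0,
                          cell_line_subtypes = c("B", "C"),
                          cell_line_shift = 0.8,
                          cell_line_shift_frac = 0.1,
                          seed = 1) {
  stopifnot(n_genes >= 1, all(group_sizes >= 2), dispersion > 0,
            n_batches >= 1, batch_sd >= 0, length(lib_size_range) == 2L,
            all(lib_size_range > 0), n_cell_lines >= 0,
            cell_line_shift_frac >= 0, cell_line_shift_frac <= 1)
  if (is.null(names(group_sizes)))
    names(group_sizes) <- LETTERS[seq_along(group_sizes)]
  if (n_cell_lines > 0 && !all(cell_line_subtypes %in% names(group_sizes)))
    stop("cell_line_subtypes must be a subset of the group names")
  structure(as.list(environment()), class = "cohort_config")
}

#' Simulate a subtype-structured expression cohort with known ground truth
#'
#' Counts are drawn as
#' \eqn{NB(\mu = \mu_0 \cdot 2^{shift + batch} \cdot s_j,\ 1/\alpha)} where
#' `shift` is the subtype signature, `batch` the per-gene batch offset, and
#' \eqn{s_j} the sample library-size factor. See [cohort_config()] for the
#' cohort structure the defaults emulate.
#'
#' @param config A [cohort_config()].
#' @return List of class `cohort_sim` with elements `counts` (integer matrix,
#'   genes x samples), `annotations` (data frame: `sample`, `definition`,
#'   `batch`, `subtype`) and `truth` (planted subtype labels, marker-gene
#'   table with true log2 fold changes, per-gene batch offsets, library-size
#'   factors, cell-line shift vector).
#' @export
simulate_cohort_counts <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  cf <- config
  if (cf$n_genes < 2500)
    warning("n_genes < 2500: downstream variable-gene selection at its ",
            "default size will fail on this cohort")
  groups <- names(cf$group_sizes)
  subtype <- rep(groups, cf$group_sizes)
  n_tissue <- length(subtype)
  n_total <- n_tissue + cf$n_cell_lines

  with_seed(cf$seed, {
    genes <- sprintf("gene%05d", seq_len(cf$n_genes))
    base_mu <- 2^stats::rnorm(cf$n_genes, cf$base_log2_mean, cf$base_log2_sd)

    # disjoint signature blocks for tumor subtypes (all groups after the first)
    shift <- matrix(0, cf$n_genes, length(groups),
                    dimnames = list(genes, groups))
    marker <- NULL
    tumor_groups <- groups[-1L]
    n_need <- cf$n_marker_genes * length(tumor_groups) + cf$n_shared_tumor_genes
    if (n_need > cf$n_genes)
      stop("marker and shared tumor blocks together exceed n_genes")
    block_idx <- sample.int(cf$n_genes, n_need)
    for (i in seq_along(tumor_groups)) {
      idx <- block_idx[((i - 1L) * cf$n_marker_genes + 1L):(i * cf$n_marker_genes)]
      shift[idx, tumor_groups[i]] <- cf$marker_lfc
      marker <- rbind(marker, data.frame(gene = genes[idx],
                                         subtype = tumor_groups[i],
                                         true_log2fc = cf$marker_lfc))
    }
    if (cf$n_shared_tumor_genes > 0) {
      idx <- block_idx[(cf$n_marker_genes * length(tumor_groups) + 1L):n_need]
      shift[idx, tumor_groups] <- cf$marker_lfc
      marker <- rbind(marker, data.frame(gene = genes[idx],
                                         subtype = "shared_tumor",
                                         true_log2fc = cf$marker_lfc))
    }

    cl_subtype <- if (cf$n_cell_lines > 0)
      sample(cf$cell_line_subtypes, cf$n_cell_lines, replace = TRUE) else character(0)
    subtype_all <- c(subtype, cl_subtype)
    is_cell_line <- c(rep(FALSE, n_tissue), rep(TRUE, cf$n_cell_lines))

    batch <- sprintf("b%d", 1L + (seq_len(n_total) - 1L) %% cf$n_batches)
    batch_off <- matrix(0, cf$n_genes, cf$n_batches,
                        dimnames = list(genes, sprintf("b%d", seq_len(cf$n_batches))))
    if (cf$n_batches > 1L)
      for (b in 2:cf$n_batches)
        batch_off[, b] <- stats::rnorm(cf$n_genes, 0, cf$batch_sd)

    cl_shift <- numeric(cf$n_genes)
    if (cf$n_cell_lines > 0 && cf$cell_line_shift_frac > 0) {
      idx <- sample.int(cf$n_genes, round(cf$cell_line_shift_frac * cf$n_genes))
      cl_shift[idx] <- cf$cell_line_shift
    }

    lib <- stats::runif(n_total, cf$lib_size_range[1], cf$lib_size_range[2])
    samples <- ifelse(is_cell_line,
                      sprintf("cl%02d", cumsum(is_cell_line)[is_cell_line]),
                      sprintf("s%03d", seq_len(n_total)))
    samples[!is_cell_line] <- sprintf("s%03d", seq_len(n_tissue))

    counts <- matrix(0L, cf$n_genes, n_total, dimnames = list(genes, samples))
    for (j in seq_len(n_total)) {
      log2mu <- log2(base_mu) + shift[, subtype_all[j]] + batch_off[, batch[j]] +
        if (is_cell_line[j]) cl_shift else 0
      counts[, j] <- stats::rnbinom(cf$n_genes, mu = 2^log2mu * lib[j],
                                    size = 1 / cf$dispersion)
    }

    annotations <- data.frame(
      sample = samples,
      definition = ifelse(is_cell_line, "cell line",
                          ifelse(subtype_all == groups[1L],
                                 "solid tissue normal", "primary solid tumor")),
      batch = batch,
      subtype = subtype_all,
      stringsAsFactors = FALSE
    )
    structure(list(
      counts = counts,
      annotations = annotations,
      truth = list(subtype = stats::setNames(subtype_all, samples),
                   markers = marker,
                   batch_offsets = batch_off,
                   lib_size = stats::setNames(lib, samples),
                   cell_line_shift = stats::setNames(cl_shift, genes))
    ), class = "cohort_sim")
  })
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat("Synthetic expression cohort:", nrow(x$counts), "genes x",
      ncol(x$counts), "samples\n")
  print(table(subtype = x$annotations$subtype, batch = x$annotations$batch))
  invisible(x)
}

#' Configuration for the xenograft tumor-growth simulator
#'
#' Defaults emulate an orthotopic MCF7 xenograft efficacy study: randomization
#' at a 230 mm^3 mean tumor volume, n = 10 animals per group, twice-weekly
#' caliper measurements over a 21-day dosing window, and per-group treatment
#' multipliers on the control exponential growth rate (negative multiplier =
#' tumor regression).
#'
#' @param n_per_group Animals per group (>= 1).
#' @param baseline Mean tumor volume at randomization, mm^3.
#' @param growth_rate Control net growth rate, 1/day.
#' @param multipliers Named vector of per-group growth-rate multipliers; the
#'   name of the multiplier equal to 1 (first such) is the conventional
#'   control arm.
#' @param cv Lognormal measurement CV applied to every volume reading.
#' @param days Measurement schedule (must include day 0).
#' @param seed Integer seed.
#' @return Object of class `xenograft_config`.
#' @export
xenograft_config <- function(n_per_group = 10,
                             baseline = 230,
                             growth_rate = 0.07,
                             multipliers = c(vehicle = 1,
                                             gedatolisib = -0.15,
                                             fulvestrant = 0.35,
                                             palbociclib = 0.28,
                                             `fulvestrant+palbociclib` = -0.10,
                                             `gedatolisib+fulvestrant` = -0.35,
                                             `gedatolisib+palbociclib` = -0.45,
                                             triplet = -0.90),
                             cv = 0.12,
                             days = c(0, 3, 7, 10, 14, 17, 21),
                             seed = 1) {
  stopifnot(n_per_group >= 1, baseline > 0, cv >= 0, 0 %in% days,
            length(multipliers) >= 1, !is.null(names(multipliers)))
  structure(as.list(environment()), class = "xenograft_config")
}

#' Simulate per-animal xenograft tumor volumes
#'
#' Each animal grows as \eqn{V(t) = V_0 \exp(r m_g t) \cdot \epsilon(t)} with
#' group multiplier \eqn{m_g} and lognormal measurement noise
#' \eqn{\epsilon}.
#'
#' @param config A [xenograft_config()].
#' @return Long data frame of class `tumor_volume_table` with columns
#'   `animal`, `group`, `day`, `volume_mm3`.
#' @export
simulate_xenograft <- function(config = xenograft_config()) {
  stopifnot(inherits(config, "xenograft_config"))
  cf <- config
  groups <- names(cf$multipliers)
  with_seed(cf$seed, {
    grid <- expand.grid(day = cf$days, animal_in_group = seq_len(cf$n_per_group),
                        group = groups, KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
    m <- cf$multipliers[grid$group]
    mu <- cf$baseline * exp(cf$growth_rate * m * grid$day)
    out <- data.frame(
      animal = sprintf("%s_%02d", grid$group, grid$animal_in_group),
      group = grid$group,
      day = grid$day,
      volume_mm3 = mu * lognormal_noise(nrow(grid), cf$cv)
    )
    out <- out[order(match(out$group, groups), out$animal, out$day), ]
    rownames(out) <- NULL
    class(out) <- c("tumor_volume_table", "data.frame")
    out
  })
}

#' Simulate a qPCR Ct table with known fold changes
#'
#' Ct values follow \eqn{Ct = baseline - \log_2(\text{relative abundance}) +
#' \mathcal{N}(0, sd)}: a gene twice as abundant amplifies one cycle earlier.
#' Reference genes have fold change 1 between groups; `ref_shifts` can plant
#' systematic Ct offsets on individual reference genes in the treated group
#' (e.g. opposite +/-0.5-cycle offsets, which the mean-of-references
#' normalizer cancels).
#'
#' @param fold_changes Named numeric vector: true treated-vs-calibrator fold
#'   change per target gene (> 0).
#' @param references Character vector of reference gene names (>= 1).
#' @param n_per_group Samples (wells) per group.
#' @param baseline_ct Baseline Ct of every gene in the calibrator group.
#' @param noise_sd Additive Gaussian Ct noise SD (>= 0).
#' @param ref_shifts Optional named vector of Ct offsets added to reference
#'   genes in the treated group.
#' @param seed Integer seed.
#' @return Long data frame of class `ct_table` with columns `sample`, `group`
#'   (`"calibrator"` / `"treated"`), `gene`, `ct`.
#' @export
simulate_ct_table <- function(fold_changes, references = c("PUM1", "SYMPK"),
                              n_per_group = 3, baseline_ct = 25,
                              noise_sd = 0, ref_shifts = NULL, seed = NULL) {
  stopifnot(length(references) >= 1L, noise_sd >= 0,
            is.numeric(fold_changes), !is.null(names(fold_changes)),
            all(fold_changes > 0))
  if (any(names(fold_changes) %in% references))
    stop("target and reference gene names must not overlap")
  genes <- c(names(fold_changes), references)
  shift <- stats::setNames(rep(0, length(genes)), genes)
  shift[names(fold_changes)] <- log2(fold_changes)
  ct_off <- stats::setNames(rep(0, length(genes)), genes)
  if (!is.null(ref_shifts)) {
    stopifnot(all(names(ref_shifts) %in% references))
    ct_off[names(ref_shifts)] <- ref_shifts
  }
  with_seed(seed, {
    grid <- expand.grid(gene = genes, rep = seq_len(n_per_group),
                        group = c("calibrator", "treated"),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    treated <- grid$group == "treated"
    ct <- baseline_ct - ifelse(treated, shift[grid$gene], 0) +
      ifelse(treated, ct_off[grid$gene], 0) +
      stats::rnorm(nrow(grid), 0, noise_sd)
    out <- data.frame(
      sample = sprintf("%s_%d", grid$group, grid$rep),
      group = grid$group, gene = grid$gene, ct = ct,
      stringsAsFactors = FALSE
    )
    class(out) <- c("ct_table", "data.frame")
    out
  })
}
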