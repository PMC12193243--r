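# adjusted Rand index between two labelings
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sc <- function(x) sum(choose(x, 2))
  expected <- sc(rowSums(tab)) * sc(colSums(tab)) / choose(n, 2)
  (sc(tab) - expected) /
    (0.5 * (sc(rowSums(tab)) + sc(colSums(tab))) - expected)
}

# two-drug Bliss-consistent Hill model used across synergy tests
two_drug_model <- function(tau = 1) {
  drug_effect_model(list(a = list(ec50 = 10, hill = 1.2, emax = 0.9),
                         b = list(ec50 = 50, hill = 1.0, emax = 0.8)),
                    tau = tau)
}

two_drug_design <- function() {
  expand.grid(a = c(0, 2, 5, 10, 20, 40, 80, 160),
              b = c(0, 10, 25, 50, 100, 200, 400, 800))
}

# hand-written viability table: one control and one treated condition with
# known start/end replicate-mean signals
manual_viability <- function(ctrl_x0, ctrl_x1, trt_x0, trt_x1, hours = 72) {
  data.frame(
    condition = rep(c("ctrl", "trt"), each = 2),
    replicate = 1L,
    time_h = c(0, hours, 0, hours),
    signal = c(ctrl_x0, ctrl_x1, trt_x0, trt_x1),
    is_control = rep(c(TRUE, FALSE), each = 2)
  )
}

# default-cohort subtype pipeline up to the variable-gene matrix
cohort_pipeline <- function(sim, n_var = 2500) {
  flt <- filter_low_counts(sim$counts, sim$annotations$definition)
  vst <- normalize_vst(flt)$vst
  corrected <- correct_batch(vst, sim$annotations$batch,
                             covariates = data.frame(
                               definition = sim$annotations$definition))
  select_variable_genes(corrected, n_var)
}

# small NB two-group count matrix with optional planted log2 fold changes
nb_two_group <- function(n_genes, n_per_group, lfc = rep(0, n_genes),
                         dispersion = 0.05, seed = 1) {
  tripletrx:::with_seed(seed, {
    base <- 2^stats::rnorm(n_genes, 5, 2)
    grp <- rep(c("ref", "alt"), each = n_per_group)
    counts <- t(vapply(seq_len(n_genes), function(g) {
      mu <- base[g] * 2^(ifelse(grp == "alt", lfc[g], 0))
      stats::rnbinom(2 * n_per_group, mu = mu, size = 1 / dispersion)
    }, numeric(2 * n_per_group)))
    storage.mode(counts) <- "integer"
    dimnames(counts) <- list(sprintf("g%05d", seq_len(n_genes)),
                             sprintf("s%03d", seq_len(2 * n_per_group)))
    list(counts = counts, groups = grp)
  })
}
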