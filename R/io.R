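#' Read a gene count matrix from TSV
#'
#' Expects a header row of sample ids with gene ids in the first column.
#' Counts must be non-negative integers; duplicate gene or sample ids are
#' rejected with the offending id named.
#'
#' @param path Path to a tab-separated file.
#' @return Integer matrix, genes x samples.
#' @export
read_counts_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  genes <- df[[1L]]
  if (anyDuplicated(genes))
    stop("duplicate gene id(s): ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  samples <- names(df)[-1L]
  if (anyDuplicated(samples))
    stop("duplicate sample id(s): ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m))
    stop("non-numeric counts in column(s): ",
         paste(samples[!vapply(df[-1L], is.numeric, logical(1))], collapse = ", "))
  bad <- which(m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad))
    stop("non-integer or negative count at gene '", genes[bad[1L, 1L]],
         "', sample '", samples[bad[1L, 2L]], "'")
  storage.mode(m) <- "integer"
  rownames(m) <- genes
  m
}

#' Write a gene count matrix to TSV
#'
#' Inverse of [read_counts_table()]; a write/read round trip is the identity.
#'
#' @param counts Integer matrix, genes x samples.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts_table <- function(counts, path) {
  stopifnot(is.matrix(counts))
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' `name<TAB>description<TAB>member...`. Empty descriptions are accepted;
#' duplicate members within a set are de-duplicated with a warning; lines
#' with fewer than three fields and duplicated set names are errors naming
#' the line.
#'
#' @param path Path to a `.gmt` file.
#' @return Named list of member-id character vectors (class
#'   `gene_set_collection`), with set descriptions in the `description`
#'   attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list(); desc <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("line ", i, ": expected at least 3 tab-separated fields, got ",
           length(f))
    nm <- f[1L]
    if (nm %in% names(sets)) stop("line ", i, ": duplicated set name '", nm, "'")
    members <- f[-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warning("set '", nm, "': duplicate members de-duplicated")
      members <- unique(members)
    }
    sets[[nm]] <- members
    desc[nm] <- f[2L]
  }
  attr(sets, "description") <- desc
  class(sets) <- "gene_set_collection"
  sets
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("Gene-set collection:", length(x), "sets; sizes",
      paste(range(lengths(x)), collapse = "-"), "\n")
  invisible(x)
}

# the stage registry: each entry reads its inputs, runs the package function,
# and writes outputs into out_dir, returning the output file names
stage_registry <- function() {
  list(
    simulate_cohort = function(params, seed, inputs, out_dir) {
      cfg <- do.call(cohort_config, c(params, list(seed = seed)))
      sim <- simulate_cohort_counts(cfg)
      write_counts_table(sim$counts, file.path(out_dir, "counts.tsv"))
      utils::write.table(sim$annotations, file.path(out_dir, "annotations.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      jsonlite::write_json(sim$truth, file.path(out_dir, "truth.json"),
                           auto_unbox = TRUE, digits = NA)
      c("counts.tsv", "annotations.tsv", "truth.json")
    },
    simulate_viability = function(params, seed, inputs, out_dir) {
      design <- utils::read.delim(inputs$design, check.names = FALSE)
      model <- do.call(drug_effect_model, params$model)
      extra <- params[setdiff(names(params), "model")]
      tab <- do.call(simulate_viability_timecourse,
                     c(list(design = design, model = model), extra,
                       list(seed = seed)))
      utils::write.table(as.data.frame(tab), file.path(out_dir, "viability.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      "viability.tsv"
    },
    simulate_xenograft = function(params, seed, inputs, out_dir) {
      cfg <- do.call(xenograft_config, c(params, list(seed = seed)))
      tab <- simulate_xenograft(cfg)
      utils::write.table(tab, file.path(out_dir, "volumes.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      "volumes.tsv"
    },
    simulate_qpcr = function(params, seed, inputs, out_dir) {
      params$fold_changes <- unlist(params$fold_changes)
      tab <- do.call(simulate_ct_table, c(params, list(seed = seed)))
      utils::write.table(tab, file.path(out_dir, "ct.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      "ct.tsv"
    },
    gr = function(params, seed, inputs, out_dir) {
      tab <- utils::read.delim(inputs$viability, check.names = FALSE)
      res <- do.call(compute_gr, c(list(tab), params))
      utils::write.table(as.data.frame(res), file.path(out_dir, "gr.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      "gr.tsv"
    },
    synergy = function(params, seed, inputs, out_dir) {
      surf <- utils::read.delim(inputs$surface, check.names = FALSE)
      res <- do.call(bliss_synergy_score,
                     c(list(surf), params, list(seed = seed)))
      utils::write.table(res$excess, file.path(out_dir, "excess.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      jsonlite::write_json(list(score = res$score,
                                classification = res$classification,
                                n_cells = res$n_cells),
                           file.path(out_dir, "synergy.json"),
                           auto_unbox = TRUE, digits = NA)
      c("excess.tsv", "synergy.json")
    },
    qpcr_ddct = function(params, seed, inputs, out_dir) {
      tab <- utils::read.delim(inputs$ct, check.names = FALSE)
      res <- do.call(ddct_relative_expression, c(list(tab), params))
      utils::write.table(as.data.frame(res), file.path(out_dir, "rq.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      "rq.tsv"
    },
    invivo_tgi = function(params, seed, inputs, out_dir) {
      tab <- utils::read.delim(inputs$volumes, check.names = FALSE)
      res <- do.call(compute_tgi, c(list(tab), params))
      jsonlite::write_json(list(tgi = res$tgi, day = res$day,
                                treated = res$treated, control = res$control,
                                p_value = res$p_value),
                           file.path(out_dir, "tgi.json"),
                           auto_unbox = TRUE, digits = NA)
      "tgi.json"
    }
  )
}

#' Run one pipeline stage from a configuration, with a manifest
#'
#' Validates the configuration (unknown keys are rejected; inputs must exist
#' before any computation starts), runs the stage under its seed, writes the
#' stage outputs into `out_dir`, and writes a `manifest.json` recording the
#' stage name, parameters, seed, md5 of every input, md5 of every output, and
#' the package version — enough to rerun deterministic and seeded stochastic
#' stages bit-identically. Nothing is written outside `out_dir`.
#'
#' @param config Named list with fields `stage` (one of `simulate_cohort`,
#'   `simulate_xenograft`, `simulate_qpcr`, `gr`, `synergy`, `qpcr_ddct`,
#'   `invivo_tgi`), optional `params` (stage parameter overrides), optional `inputs` (named
#'   input paths), `seed`, and `out_dir`.
#' @return The manifest, invisibly.
#' @export
run_stage <- function(config) {
  allowed <- c("stage", "params", "inputs", "seed", "out_dir")
  unknown <- setdiff(names(config), allowed)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  registry <- stage_registry()
  if (is.null(config$stage) || !config$stage %in% names(registry))
    stop("config$stage must be one of: ",
         paste(names(registry), collapse = ", "))
  if (is.null(config$out_dir)) stop("config$out_dir is required")
  inputs <- config$inputs %||% list()
  paths <- as.character(unlist(inputs))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("missing input file(s): ", paste(missing, collapse = ", "))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  seed <- config$seed %||% NULL
  outputs <- registry[[config$stage]](config$params %||% list(), seed,
                                      inputs, config$out_dir)
  manifest <- list(
    stage = config$stage,
    params = config$params %||% list(),
    seed = seed,
    inputs = lapply(inputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    outputs = lapply(stats::setNames(outputs, outputs), function(f)
      unname(tools::md5sum(file.path(config$out_dir, f)))),
    package_version = as.character(utils::packageVersion("tripletrx"))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

#' Compare the parameters of two stage manifests
#'
#' @param m1,m2 Manifests (lists as returned by [run_stage()], or paths to
#'   `manifest.json` files).
#' @return Character vector of parameter keys whose values differ (including
#'   keys present in only one manifest), prefixed `params.`; plus `stage.`
#'   and `seed.` entries when those differ.
#' @export
manifest_diff <- function(m1, m2) {
  load_m <- function(m) if (is.character(m)) jsonlite::read_json(m) else m
  m1 <- load_m(m1); m2 <- load_m(m2)
  out <- character(0)
  if (!identical(m1$stage, m2$stage)) out <- c(out, "stage")
  if (!identical(m1$seed %||% NULL, m2$seed %||% NULL)) out <- c(out, "seed")
  keys <- union(names(m1$params), names(m2$params))
  for (k in keys)
    if (!isTRUE(all.equal(m1$params[[k]], m2$params[[k]])))
      out <- c(out, paste0("params.", k))
  out
}

#' Read a long-format viability table from TSV
#'
#' Columns: `condition`, `replicate`, dose columns (nM), `time_h`, `signal`,
#' `is_control`.
#'
#' @param path Path to a tab-separated file.
#' @return A `viability_table` data frame.
#' @export
read_viability_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE)
  need <- c("condition", "time_h", "signal", "is_control")
  if (!all(need %in% names(df)))
    stop("viability table must have columns: ", paste(need, collapse = ", "))
  class(df) <- c("viability_table", "data.frame")
  df
}
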