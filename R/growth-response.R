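#' Normalize assay values to a vehicle control
#'
#' Linear percent-of-control scaling: the control mean maps to 1.
#'
#' @param values Numeric vector of raw readouts.
#' @param control_values Numeric vector of vehicle-control readouts.
#' @return `values / mean(control_values)`.
#' @examples
#' normalize_to_control(50, c(90, 110))  # 0.5
#' @export
normalize_to_control <- function(values, control_values) {
  m <- mean(control_values)
  if (!is.finite(m) || m <= 0)
    stop("control mean must be positive; got ", format(m))
  values / m
}

#' Growth-rate (GR) metrics from a two-timepoint viability table
#'
#' For each condition the growth rate is
#' \eqn{k = \log_2(x(t)/x(0)) / t} (doublings per hour), computed from
#' replicate-mean signals, and the GR value is
#' \deqn{GR = 2^{k_{treated}/k_{control}} - 1.}
#' GR = 1 means the treated population grows exactly like the control,
#' GR = 0 complete cytostasis (no net growth), GR < 0 cytotoxicity, and
#' GR = -1 complete killing. GR inhibition is reported as
#' \eqn{100 (1 - GR)} percent. Per-replicate GR values (each replicate's k
#' against the control replicate-mean k) are attached for dispersion
#' estimates.
#'
#' @param table A `viability_table` (long format with columns `condition`,
#'   `replicate`, `time_h`, `signal`, `is_control`), e.g. from
#'   [simulate_viability_timecourse()] or [read_viability_table()].
#' @param duration Treatment window in hours; default the span between the
#'   first and last timepoint in the table.
#' @return Data frame of class `gr_result`: one row per condition with
#'   `k_treated`, `k_control`, `gr`, `gr_inhibition_pct`, dose columns carried
#'   over, and a `replicate_gr` attribute.
#' @export
compute_gr <- function(table, duration = NULL) {
  need <- c("condition", "time_h", "signal", "is_control")
  if (!all(need %in% names(table)))
    stop("table must have columns: ", paste(need, collapse = ", "))
  t0 <- min(table$time_h)
  t1 <- if (is.null(duration)) max(table$time_h) else t0 + duration
  tab <- table[table$time_h %in% c(t0, t1), ]
  if (t1 <= t0) stop("duration must be positive")
  if (!any(tab$is_control))
    stop("no control condition present; GR is undefined without k(0)")
  if (any(tab$signal <= 0))
    stop("all signals must be positive after background subtraction")

  mean_sig <- stats::aggregate(signal ~ condition + time_h, tab, mean)
  x0 <- mean_sig$signal[mean_sig$time_h == t0]
  names(x0) <- mean_sig$condition[mean_sig$time_h == t0]
  x1 <- mean_sig$signal[mean_sig$time_h == t1]
  names(x1) <- mean_sig$condition[mean_sig$time_h == t1]
  conds <- sort(unique(tab$condition))
  if (!all(conds %in% names(x0)) || !all(conds %in% names(x1)))
    stop("every condition needs signals at both timepoints")

  k <- log2(x1[conds] / x0[conds]) / (t1 - t0)
  ctrl_conds <- unique(tab$condition[tab$is_control])
  k0 <- mean(k[ctrl_conds])
  if (k0 <= 0)
    stop("control growth rate k(0) <= 0: GR is undefined for a non-growing control")

  gr <- 2^(k / k0) - 1

  # per-replicate GR against the replicate-mean control growth rate
  rep_tab <- tab[order(tab$condition, tab$replicate, tab$time_h), ]
  key <- interaction(rep_tab$condition, rep_tab$replicate, drop = TRUE)
  r0 <- rep_tab$signal[rep_tab$time_h == t0]
  r1 <- rep_tab$signal[rep_tab$time_h == t1]
  rep_k <- log2(r1 / r0) / (t1 - t0)
  rep_gr <- data.frame(condition = rep_tab$condition[rep_tab$time_h == t0],
                       replicate = rep_tab$replicate[rep_tab$time_h == t0],
                       gr = 2^(rep_k / k0) - 1)

  dose_cols <- setdiff(names(tab),
                       c("condition", "replicate", "time_h", "signal", "is_control"))
  first <- tab[!duplicated(tab$condition), c("condition", dose_cols), drop = FALSE]
  out <- data.frame(condition = conds,
                    first[match(conds, first$condition), dose_cols, drop = FALSE],
                    k_treated = unname(k[conds]),
                    k_control = k0,
                    gr = unname(gr[conds]),
                    gr_inhibition_pct = 100 * (1 - unname(gr[conds])),
                    row.names = NULL, check.names = FALSE)
  attr(out, "replicate_gr") <- rep_gr
  attr(out, "k0") <- k0
  class(out) <- c("gr_result", "data.frame")
  out
}

# 4PL response at dose c (c > 0): ceiling at dose -> 0, floor at dose -> Inf
# for slope > 0
fourpl <- function(dose, floor, ceiling, log_ec50, slope) {
  floor + (ceiling - floor) / (1 + exp(slope * (log(dose) - log_ec50)))
}

#' Fit a four-parameter log-logistic dose-response curve
#'
#' Bounded Levenberg-Marquardt least squares of
#' \deqn{f(c) = floor + \frac{ceiling - floor}{1 + (c/EC_{50})^{slope}}}
#' on GR values or relative viability. Zero doses anchor the top of the curve
#' and are placed at a pseudo-dose two decades below the smallest tested
#' positive dose for log-dose fitting. The half-effect concentration (GR50
#' for GR curves, IC50 for relative viability) is the dose where the fitted
#' curve crosses 0.5, solved analytically from the fitted parameters; it is
#' reported as `Inf` (flag `reached = FALSE`) when the curve never crosses
#' 0.5 within the tested dose range.
#'
#' @param doses Numeric vector of doses (>= 0; at least 4 distinct values).
#' @param responses Numeric vector of responses (same length).
#' @param response_kind `"gr"` or `"relative_viability"`; only affects the
#'   label of the half-effect dose.
#' @return Object of class `dose_response_fit` with elements `coefficients`
#'   (`floor`, `ceiling`, `ec50`, `slope`), `half_effect` (the GR50/IC50),
#'   `reached`, `response_max` (fitted response at the largest tested dose,
#'   the GRmax analogue), `rss`, `converged`, `response_kind`, `data`.
#' @seealso [predict.dose_response_fit()], [coef.dose_response_fit()]
#' @export
fit_dose_response <- function(doses, responses,
                              response_kind = c("gr", "relative_viability")) {
  response_kind <- match.arg(response_kind)
  stopifnot(length(doses) == length(responses), all(doses >= 0),
            all(is.finite(responses)))
  if (length(unique(doses)) < 4L)
    stop("need at least 4 distinct doses to fit a 4-parameter curve")
  pos <- doses[doses > 0]
  if (length(pos) == 0L) stop("all doses are zero")
  pseudo <- min(pos) / 100
  d <- ifelse(doses == 0, pseudo, doses)

  span <- max(responses) - min(responses)
  if (span < 1e-10) {
    # perfectly flat response: the constant curve is the least-squares fit and
    # no 0.5 crossing exists unless the constant is 0.5 itself
    lvl <- mean(responses)
    out <- list(coefficients = c(floor = lvl, ceiling = lvl, ec50 = NA_real_,
                                 slope = NA_real_),
                half_effect = Inf, reached = FALSE, response_max = lvl,
                rss = sum((responses - lvl)^2), converged = TRUE,
                response_kind = response_kind, pseudo_dose = pseudo,
                data = data.frame(dose = doses, response = responses))
    class(out) <- "dose_response_fit"
    return(out)
  }
  start <- c(floor = min(responses), ceiling = max(responses),
             log_ec50 = mean(log(range(pos))), slope = 1)
  lower <- c(floor = min(responses) - max(span, 0.1),
             ceiling = min(responses),
             log_ec50 = log(pseudo) - 3, slope = 0.05)
  upper <- c(floor = max(responses),
             ceiling = max(responses) + max(span, 0.1),
             log_ec50 = log(max(pos)) + 3, slope = 20)

  fit <- tryCatch(
    minpack.lm::nlsLM(
      responses ~ fourpl(d, floor, ceiling, log_ec50, slope),
      start = start, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                           ptol = 1e-14)),
    error = function(e) e)

  if (inherits(fit, "error")) {
    out <- list(coefficients = c(floor = NA_real_, ceiling = NA_real_,
                                 ec50 = NA_real_, slope = NA_real_),
                half_effect = NA_real_, reached = FALSE,
                response_max = NA_real_, rss = NA_real_, converged = FALSE,
                message = conditionMessage(fit),
                response_kind = response_kind,
                data = data.frame(dose = doses, response = responses))
    class(out) <- "dose_response_fit"
    return(out)
  }

  p <- stats::coef(fit)
  cf <- c(floor = unname(p["floor"]), ceiling = unname(p["ceiling"]),
          ec50 = exp(unname(p["log_ec50"])), slope = unname(p["slope"]))

  # analytic crossing of 0.5: exp(slope*(log c - log ec50)) = (ceiling-0.5)/(0.5-floor)
  half <- Inf
  if (cf["floor"] < 0.5 && cf["ceiling"] > 0.5) {
    ratio <- (cf["ceiling"] - 0.5) / (0.5 - cf["floor"])
    half <- unname(cf["ec50"] * ratio^(1 / cf["slope"]))
  }
  reached <- is.finite(half) && half <= max(pos)

  out <- list(coefficients = cf,
              half_effect = unname(half),
              reached = reached,
              response_max = unname(fourpl(max(pos), p["floor"], p["ceiling"],
                                           p["log_ec50"], p["slope"])),
              rss = sum(stats::residuals(fit)^2),
              converged = TRUE,
              response_kind = response_kind,
              pseudo_dose = pseudo,
              data = data.frame(dose = doses, response = responses))
  class(out) <- "dose_response_fit"
  out
}

#' @export
coef.dose_response_fit <- function(object, ...) object$coefficients

#' Evaluate a fitted dose-response curve
#'
#' @param object A `dose_response_fit`.
#' @param newdata Numeric vector of doses (zero doses use the fit's
#'   pseudo-dose anchor).
#' @param ... Unused.
#' @return Fitted responses.
#' @export
predict.dose_response_fit <- function(object, newdata = NULL, ...) {
  if (!object$converged) stop("fit did not converge; no predictions available")
  d <- if (is.null(newdata)) object$data$dose else newdata
  d <- ifelse(d == 0, object$pseudo_dose, d)
  cf <- object$coefficients
  if (is.na(cf["ec50"])) return(rep(unname(cf["floor"]), length(d)))  # flat fit
  fourpl(d, cf["floor"], cf["ceiling"], log(cf["ec50"]), cf["slope"])
}

#' @export
residuals.dose_response_fit <- function(object, ...) {
  object$data$response - predict(object)
}

#' @export
print.dose_response_fit <- function(x, ...) {
  lbl <- if (x$response_kind == "gr") "GR50" else "IC50"
  cat("4PL dose-response fit (", x$response_kind, ")\n", sep = "")
  if (!x$converged) {
    cat("  did not converge:", x$message, "\n")
    return(invisible(x))
  }
  cat(sprintf("  floor = %.4g, ceiling = %.4g, EC50 = %.4g, slope = %.4g\n",
              x$coefficients["floor"], x$coefficients["ceiling"],
              x$coefficients["ec50"], x$coefficients["slope"]))
  cat(sprintf("  %s = %s%s, response at max dose = %.4g, RSS = %.3g\n", lbl,
              format(x$half_effect, digits = 4),
              if (x$reached) "" else " (not reached in tested range)",
              x$response_max, x$rss))
  invisible(x)
}

#' @export
plot.dose_response_fit <- function(x, n = 200, ...) {
  d <- x$data
  pos <- d$dose[d$dose > 0]
  grid <- exp(seq(log(min(pos) / 100), log(max(pos)), length.out = n))
  plot(ifelse(d$dose == 0, min(pos) / 100, d$dose), d$response, log = "x",
       xlab = "dose", ylab = x$response_kind, ...)
  if (x$converged) graphics::lines(grid, predict(x, grid))
  if (is.finite(x$half_effect)) graphics::abline(v = x$half_effect, lty = 2)
  invisible(x)
}

#' Relative expression by the delta-delta-Ct method
#'
#' Per sample, the reference Ct is the arithmetic mean of the reference-gene
#' Cts (the geometric-mean normalizer in abundance space);
#' \eqn{\Delta Ct = Ct_{target} - Ct_{ref}} is averaged within groups,
#' \eqn{\Delta\Delta Ct} is taken against the calibrator group, and relative
#' quantity is \eqn{RQ = 2^{-\Delta\Delta Ct}}.
#'
#' @param ct_table Long data frame with columns `sample`, `group`, `gene`,
#'   `ct` (see [simulate_ct_table()]).
#' @param targets Character vector of target genes.
#' @param references Character vector of reference genes (>= 1); every sample
#'   must have a Ct for each.
#' @param calibrator Group label used as calibrator (RQ = 1 by construction).
#' @return Data frame of class `rq_result`: `target`, `group`, `delta_ct`,
#'   `delta_delta_ct`, `rq`.
#' @export
ddct_relative_expression <- function(ct_table, targets, references,
                                     calibrator = "calibrator") {
  need <- c("sample", "group", "gene", "ct")
  stopifnot(all(need %in% names(ct_table)), length(references) >= 1L)
  if (!calibrator %in% ct_table$group)
    stop("calibrator group '", calibrator, "' not present in the table")
  ref_tab <- ct_table[ct_table$gene %in% references, ]
  ref_n <- table(ref_tab$sample)
  all_samples <- unique(ct_table$sample)
  bad <- setdiff(all_samples, names(ref_n)[ref_n == length(references)])
  if (length(bad))
    stop("samples missing reference-gene Cts: ", paste(bad, collapse = ", "))
  ref_ct <- tapply(ref_tab$ct, ref_tab$sample, mean)

  out <- do.call(rbind, lapply(targets, function(tg) {
    tt <- ct_table[ct_table$gene == tg, ]
    if (nrow(tt) == 0L) stop("target gene '", tg, "' not in the table")
    dct <- tt$ct - ref_ct[tt$sample]
    grp_dct <- tapply(dct, tt$group, mean)
    ddct <- grp_dct - grp_dct[[calibrator]]
    data.frame(target = tg, group = names(grp_dct),
               delta_ct = as.numeric(grp_dct),
               delta_delta_ct = as.numeric(ddct),
               rq = 2^(-as.numeric(ddct)), row.names = NULL)
  }))
  class(out) <- c("rq_result", "data.frame")
  out
}
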