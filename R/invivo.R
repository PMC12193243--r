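#' Tumor volume from caliper measurements
#'
#' \eqn{V = L \cdot W^2 / 2} (mm^3), the standard prolate-ellipsoid
#' approximation. Length is expected to be the longer dimension; pairs with
#' `width > length` are swapped with a warning.
#'
#' @param length,width Caliper measurements in mm (vectors, > 0).
#' @return Volumes in mm^3.
#' @examples
#' caliper_volume(10, 8)  # 320
#' @export
caliper_volume <- function(length, width) {
  stopifnot(base::length(length) == base::length(width))
  if (any(length <= 0 | width <= 0))
    stop("caliper measurements must be positive")
  swap <- width > length
  if (any(swap)) {
    warning(sum(swap), " measurement pair(s) had width > length; swapped")
    tmp <- length[swap]; length[swap] <- width[swap]; width[swap] <- tmp
  }
  length * width^2 / 2
}

#' Percent tumor growth inhibition (TGI) at a study day
#'
#' \deqn{\%TGI = \left[1 - \frac{\bar V_{t,X} - \bar V_{t,0}}
#'   {\bar V_{c,X} - \bar V_{c,0}}\right] \times 100}
#' where the bars are group means of the treated (t) and control (c) arms at
#' randomization (day 0) and day X. TGI = 100\% when the treated group mean
#' is back at its own baseline; TGI > 100\% indicates net regression. Animals
#' missing the day-X measurement are excluded (with a message) from both the
#' day-X and day-0 means.
#'
#' @param table Long data frame with columns `animal`, `group`, `day`,
#'   `volume_mm3` (see [simulate_xenograft()]); day 0 must be present for
#'   every animal used.
#' @param treated,control Group labels.
#' @param day Study day X.
#' @param ancova If `TRUE` (default) also report the ANCOVA p-value of the
#'   treated-vs-control contrast at day X (see [ancova_treatment_effect()]).
#' @return Object of class `tgi_result`: `tgi`, group means used, `p_value`
#'   (or `NA` if `ancova = FALSE`), `day`, group labels, animals used.
#' @export
compute_tgi <- function(table, treated, control, day, ancova = TRUE) {
  need <- c("animal", "group", "day", "volume_mm3")
  stopifnot(all(need %in% names(table)))
  for (g in c(treated, control))
    if (!g %in% table$group) stop("group '", g, "' not in the table")

  group_means <- function(g) {
    tab <- table[table$group == g, ]
    at_x <- unique(tab$animal[tab$day == day])
    at_0 <- unique(tab$animal[tab$day == 0])
    if (!length(at_x)) stop("group '", g, "' has no day-", day, " measurements")
    missing0 <- setdiff(at_x, at_0)
    if (length(missing0))
      stop("group '", g, "' animals missing day 0: ",
           paste(missing0, collapse = ", "))
    dropped <- setdiff(at_0, at_x)
    if (length(dropped))
      message("excluding animal(s) without day-", day, " measurement in '",
              g, "': ", paste(dropped, collapse = ", "))
    use <- tab$animal %in% at_x
    c(v0 = mean(tab$volume_mm3[use & tab$day == 0]),
      vx = mean(tab$volume_mm3[use & tab$day == day]),
      n = length(at_x))
  }
  mt <- group_means(treated)
  mc <- group_means(control)
  dvc <- mc[["vx"]] - mc[["v0"]]
  if (dvc == 0)
    stop("control group mean volume did not change by day ", day,
         "; TGI is undefined")
  tgi <- 100 * (1 - (mt[["vx"]] - mt[["v0"]]) / dvc)

  p <- NA_real_
  if (ancova) {
    an <- tryCatch(
      ancova_treatment_effect(table[table$group %in% c(treated, control), ],
                              day = day, comparator = control),
      error = function(e) NULL)
    if (!is.null(an)) p <- an$p_value[an$group == treated]
  }
  structure(list(tgi = unname(tgi), treated = treated, control = control,
                 day = day, p_value = p,
                 means = data.frame(group = c(treated, control),
                                    v0 = c(mt[["v0"]], mc[["v0"]]),
                                    vx = c(mt[["vx"]], mc[["vx"]]),
                                    n = c(mt[["n"]], mc[["n"]]))),
            class = "tgi_result")
}

#' @export
print.tgi_result <- function(x, ...) {
  cat(sprintf("%%TGI (%s vs %s, day %g): %.1f%%", x$treated, x$control,
              x$day, x$tgi))
  if (!is.na(x$p_value)) cat(sprintf("  (ANCOVA p = %.3g)", x$p_value))
  cat("\n")
  print(x$means, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Percent tumor regression and partial/complete calls
#'
#' \eqn{\%regression = -(V_X - V_0)/V_0 \times 100} per animal. Calls use the
#' 30\%/80\% convention with inclusive thresholds: `none` below 30\%,
#' `partial` at 30\% or more, `complete` at 80\% or more shrinkage from the
#' pretreatment volume.
#'
#' @param v0 Pretreatment volume(s), > 0.
#' @param vx Volume(s) at day X.
#' @return Data frame: `percent_regression`, `call` (factor
#'   none/partial/complete).
#' @examples
#' percent_regression(230, 46)   # 80%, complete
#' percent_regression(230, 150)  # ~34.8%, partial
#' @export
percent_regression <- function(v0, vx) {
  stopifnot(length(v0) == length(vx))
  if (any(v0 <= 0)) stop("pretreatment volumes must be positive")
  pct <- -(vx - v0) / v0 * 100
  call <- cut(pct, breaks = c(-Inf, 30, 80, Inf),
              labels = c("none", "partial", "complete"), right = FALSE)
  data.frame(percent_regression = pct, call = call)
}

#' ANCOVA treatment-effect test on log tumor volumes
#'
#' Fits `log(V_X) ~ group + log(V_0)` by ordinary least squares with the
#' comparator group as reference level, and reports the per-group contrast
#' t-tests against the comparator. Log volumes are used because tumor growth
#' noise is multiplicative.
#'
#' @param table Long volume table as in [compute_tgi()].
#' @param day Study day X.
#' @param comparator Reference group (e.g. `"vehicle"`).
#' @return Object of class `ancova_result`: a data frame (`group`,
#'   `estimate` — log-volume difference adjusted for baseline, `se`, `t`,
#'   `p_value`) with the fitted `lm` in the `fit` attribute.
#' @export
ancova_treatment_effect <- function(table, day, comparator) {
  need <- c("animal", "group", "day", "volume_mm3")
  stopifnot(all(need %in% names(table)))
  if (!comparator %in% table$group)
    stop("comparator group '", comparator, "' not in the table")
  v0 <- table[table$day == 0, c("animal", "group", "volume_mm3")]
  vx <- table[table$day == day, c("animal", "volume_mm3")]
  d <- merge(v0, vx, by = "animal", suffixes = c("_0", "_x"))
  if (any(table(d$group) < 2L))
    stop("every group needs at least 2 animals with day-0 and day-", day,
         " measurements")
  d$group <- stats::relevel(factor(d$group), ref = comparator)
  fit <- stats::lm(log(volume_mm3_x) ~ group + log(volume_mm3_0), data = d)
  if (any(is.na(stats::coef(fit))))
    stop("singular ANCOVA design: ",
         paste(names(which(is.na(stats::coef(fit)))), collapse = ", "))
  sm <- summary(fit)$coefficients
  rows <- grep("^group", rownames(sm))
  out <- data.frame(group = sub("^group", "", rownames(sm)[rows]),
                    estimate = sm[rows, 1L], se = sm[rows, 2L],
                    t = sm[rows, 3L], p_value = sm[rows, 4L],
                    row.names = NULL)
  attr(out, "fit") <- fit
  attr(out, "comparator") <- comparator
  class(out) <- c("ancova_result", "data.frame")
  out
}
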