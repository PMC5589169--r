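#' Normalize patient values to the control-group mean
#'
#' Expresses each patient's value relative to the healthy-control (G0)
#' average, so GP and HbA1c trajectories can share one axis.
#'
#' @param values Numeric vector.
#' @param control_mean Non-zero G0 mean of the same quantity.
#' @return `values / control_mean`.
#' @export
normalize_to_control <- function(values, control_mean) {
  if (!is.numeric(control_mean) || length(control_mean) != 1L ||
      control_mean == 0)
    stop("control mean must be a non-zero scalar", call. = FALSE)
  values / control_mean
}

#' Coefficient of variation
#'
#' Sample SD over the absolute mean: the extent of variability in
#' relation to the level of the quantity, the yardstick by which the GP
#' readout's stability is compared with HbA1c's.
#'
#' @param values Numeric vector with non-zero mean.
#' @return Non-negative scalar.
#' @export
coefficient_of_variation <- function(values) {
  m <- mean(values)
  if (m == 0) stop("mean is zero; CV undefined", call. = FALSE)
  stats::sd(values) / abs(m)
}

#' Ordinary least-squares fit of y on x
#'
#' @param x,y Numeric vectors, `length >= 2`, `x` not constant.
#' @return A `regression_fit`: list with `slope`, `intercept`,
#'   `r_squared`, `n`.
#' @export
fit_linear_regression <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 2L) stop("need at least 2 points", call. = FALSE)
  if (stats::sd(x) == 0) stop("constant predictor", call. = FALSE)
  fit <- stats::lm(y ~ x)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
    n = length(x)
  ), class = "regression_fit")
}

#' Pairwise Welch comparisons of a quantity across patient groups
#'
#' Two-sided Welch (unequal-variance) t-tests for every group pair, with
#' no multiplicity correction, flagged at the 0.05 and 0.001 levels.
#' Groups with fewer than 2 patients are excluded (and listed).
#'
#' @param values Numeric per-patient quantity.
#' @param groups Group labels per patient.
#' @return A `group_comparison`: per-group n/mean/SD table, a data.frame
#'   of pairwise tests (`p_value`, `significant_05`, `significant_001`),
#'   and `excluded` group names.
#' @export
group_comparison <- function(values, groups) {
  y <- group_factor(groups)
  stopifnot(length(values) == length(y), !anyNA(y))
  counts <- table(y)
  present <- names(counts)[counts >= 2L]
  excluded <- names(counts)[counts > 0L & counts < 2L]
  summary <- data.frame(
    group = present,
    n = as.integer(counts[present]),
    mean = vapply(present, function(g) mean(values[y == g]), 0),
    sd = vapply(present, function(g) stats::sd(values[y == g]), 0),
    stringsAsFactors = FALSE
  )
  pairs <- utils::combn(present, 2, simplify = FALSE)
  tests <- do.call(rbind, lapply(pairs, function(p) {
    tt <- stats::t.test(values[y == p[1]], values[y == p[2]],
                        var.equal = FALSE)
    data.frame(group_a = p[1], group_b = p[2],
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_value = tt$p.value,
               significant_05 = tt$p.value < 0.05,
               significant_001 = tt$p.value < 0.001,
               stringsAsFactors = FALSE)
  }))
  structure(list(summary = summary, tests = tests, excluded = excluded),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  print(x$summary, row.names = FALSE)
  print(x$tests[, c("group_a", "group_b", "p_value")], row.names = FALSE)
  invisible(x)
}

#' Therapy separation in the (insulin dose, mean GP) plane
#'
#' Reports how well a straight line `GP = intercept + slope * insulin`
#' separates pump (CSII) from injection (MDI) patients, encoding the
#' observation that pump therapy associates with higher membrane
#' fluidity (lower GP): CSII patients are expected below the line, MDI
#' above. The line is a reporting device, not a fitted classifier; when
#' not supplied, a horizontal line at the midpoint of the two therapy
#' groups' mean GP is used.
#'
#' @param gp_mean Per-patient mean GP (diabetic patients only).
#' @param insulin_u_per_kg Per-patient insulin dose (U/kg).
#' @param therapy `"MDI"` or `"CSII"` per patient.
#' @param line Optional `list(intercept =, slope =)`.
#' @return A `therapy_separation`: the line used, per-therapy counts on
#'   each side, and `separation_fraction` (fraction of patients on their
#'   expected side).
#' @export
therapy_separation_report <- function(gp_mean, insulin_u_per_kg, therapy,
                                      line = NULL) {
  stopifnot(length(gp_mean) == length(insulin_u_per_kg),
            length(gp_mean) == length(therapy))
  if (length(gp_mean) == 0L)
    stop("no diabetic patients to assess", call. = FALSE)
  if (!all(therapy %in% c("MDI", "CSII")))
    stop("therapy must be MDI or CSII for every patient", call. = FALSE)
  if (is.null(line)) {
    mu <- vapply(c("MDI", "CSII"),
                 function(t) mean(gp_mean[therapy == t]), 0)
    line <- list(intercept = mean(mu), slope = 0)
  }
  expected <- line$intercept + line$slope * insulin_u_per_kg
  below <- gp_mean < expected
  on_side <- ifelse(therapy == "CSII", below, !below)
  counts <- data.frame(
    therapy = c("MDI", "CSII"),
    n = c(sum(therapy == "MDI"), sum(therapy == "CSII")),
    below_line = c(sum(below & therapy == "MDI"),
                   sum(below & therapy == "CSII")),
    stringsAsFactors = FALSE
  )
  structure(list(
    line = line,
    counts = counts,
    separation_fraction = mean(on_side)
  ), class = "therapy_separation")
}

#' Full descriptive statistics report for a cohort
#'
#' The comparative analyses around the classifier: per-group GP and
#' HbA1c comparisons (Welch tests), normalization to the control means,
#' coefficients of variation, regressions of the normalized quantities
#' on disease duration (diabetics), per-group regressions of mean GP on
#' cholesterol and LDL, and the therapy-separation assessment.
#'
#' @param tab Cohort covariate table ([cohort_table()]).
#' @param gp_mean Per-patient mean GP, aligned with `tab` rows.
#' @param separation_line Optional line for
#'   [therapy_separation_report()].
#' @return A nested list (serializable to JSON).
#' @export
cohort_statistics_report <- function(tab, gp_mean, separation_line = NULL) {
  stopifnot(nrow(tab) == length(gp_mean))
  g0 <- tab$group == "G0"
  out <- list()
  out$gp_by_group <- group_comparison(gp_mean, tab$group)
  out$hba1c_by_group <- group_comparison(tab$hba1c_pct, tab$group)
  if (any(g0)) {
    gp0 <- mean(gp_mean[g0])
    hb0 <- mean(tab$hba1c_pct[g0])
    gp_norm <- normalize_to_control(gp_mean, gp0)
    hb_norm <- normalize_to_control(tab$hba1c_pct, hb0)
    out$control_means <- list(gp = gp0, hba1c = hb0)
    out$cv <- list(gp = coefficient_of_variation(gp_mean[g0]),
                   hba1c = coefficient_of_variation(tab$hba1c_pct[g0]))
    dia <- tab$group != "G0"
    if (sum(dia) >= 2L && stats::sd(tab$duration_years[dia]) > 0) {
      out$duration_regression <- list(
        gp = unclass(fit_linear_regression(tab$duration_years[dia],
                                           gp_norm[dia])),
        hba1c = unclass(fit_linear_regression(tab$duration_years[dia],
                                              hb_norm[dia]))
      )
    }
  }
  out$lipid_regressions <- lapply(setNames(GROUP_LEVELS, GROUP_LEVELS),
    function(g) {
      sel <- tab$group == g
      if (sum(sel) < 3L) return(NULL)
      list(
        cholesterol = unclass(
          fit_linear_regression(tab$cholesterol_mg_dl[sel], gp_mean[sel])),
        ldl = unclass(
          fit_linear_regression(tab$ldl_mg_dl[sel], gp_mean[sel]))
      )
    })
  dia <- tab$therapy %in% c("MDI", "CSII")
  if (any(dia)) {
    out$therapy_separation <- unclass(
      therapy_separation_report(gp_mean[dia], tab$insulin_u_per_kg[dia],
                                tab$therapy[dia], separation_line))
  }
  out
}
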