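#' Fit an external-standard calibration curve
#'
#' Ordinary least squares `response = slope * conc + intercept`, with limits
#' of detection and quantitation derived from the residual standard
#' deviation: `LOD = 3.3 sigma / slope`, `LOQ = 10 sigma / slope`.
#'
#' @param concs Standard concentrations in ug/mL (>= 3 distinct values).
#' @param responses Detector responses (peak areas).
#' @return Object of class `calibration_curve`.
#' @export
fit_calibration <- function(concs, responses) {
  stopifnot(length(concs) == length(responses))
  if (length(unique(concs)) < 3) {
    stop("calibration needs at least 3 distinct concentrations")
  }
  fit <- stats::lm(responses ~ concs)
  slope <- unname(stats::coef(fit)[2L])
  if (slope == 0) stop("zero calibration slope")
  sigma <- stats::sigma(fit)
  calibration_curve(
    slope = slope, intercept = unname(stats::coef(fit)[1L]),
    range = range(concs), r2 = summary(fit)$r.squared,
    lod = 3.3 * sigma / abs(slope), loq = 10 * sigma / abs(slope),
    sigma_resid = sigma)
}

#' Construct a calibration curve from known parameters
#'
#' @param slope,intercept Line parameters (response units per ug/mL).
#' @param range Length-2 tested concentration range (ug/mL), low < high.
#' @param r2 Coefficient of determination in `[0, 1]`.
#' @param lod,loq Limits of detection/quantitation (ug/mL).
#' @param sigma_resid Residual standard deviation, if known.
#' @param analyte Optional analyte name.
#' @return Object of class `calibration_curve`.
#' @export
calibration_curve <- function(slope, intercept, range, r2 = NA_real_,
                              lod = NA_real_, loq = NA_real_,
                              sigma_resid = NA_real_, analyte = NULL) {
  stopifnot(slope != 0, length(range) == 2, range[1] < range[2],
            is.na(r2) || (r2 >= 0 && r2 <= 1))
  structure(list(slope = slope, intercept = intercept, range = range,
                 r2 = r2, lod = lod, loq = loq, sigma_resid = sigma_resid,
                 analyte = analyte),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat("Calibration", if (!is.null(x$analyte)) paste0("(", x$analyte, ")"),
      ": Y =", format(x$slope, digits = 10), "X",
      if (x$intercept >= 0) "+" else "-", format(abs(x$intercept), digits = 9),
      "\n")
  cat("  range ", x$range[1], "-", x$range[2], " ug/mL, R^2 = ", x$r2,
      ", LOD = ", x$lod, ", LOQ = ", x$loq, " ug/mL\n", sep = "")
  invisible(x)
}

#' Concentration from a detector response
#'
#' Inverts the calibration line: `X = (response - intercept)/slope`, and
#' flags values below the LOQ/LOD or outside the tested range.
#'
#' @param response Detector response(s).
#' @param c A [calibration_curve()].
#' @return Data frame with `conc_ugml`, `below_lod`, `below_loq`,
#'   `outside_range`.
#' @export
quantify <- function(response, c) {
  stopifnot(inherits(c, "calibration_curve"))
  conc <- (response - c$intercept) / c$slope
  data.frame(
    conc_ugml = conc,
    below_lod = if (is.na(c$lod)) NA else conc < c$lod,
    below_loq = if (is.na(c$loq)) NA else conc < c$loq,
    outside_range = conc < c$range[1] | conc > c$range[2])
}

#' Marker dose equivalent to its content in an extract dose
#'
#' The dose of a pure marker that matches the amount contained in a given
#' extract dose: `content_fraction * extract_dose`.
#'
#' @param content_fraction Mass fraction of the marker in the extract, in
#'   `[0, 1]`.
#' @param extract_dose Extract dose (mg/kg, > 0).
#' @return Marker dose in mg/kg.
#' @export
hecm_dose <- function(content_fraction, extract_dose) {
  stopifnot(all(content_fraction >= 0), all(content_fraction <= 1),
            all(extract_dose > 0))
  content_fraction * extract_dose
}

#' Hepatotoxic equivalence test (two one-sided t tests, 90% CI)
#'
#' Tests whether a candidate marker combination is toxicologically
#' equivalent to the whole extract. Enzyme activities are log-transformed;
#' the 90% confidence interval of the candidate/original toxicity ratio is
#'
#' `exp( (Yb - Yh) -/+ t(0.95, n1+n2-2) * sigma_w * sqrt(0.5 (1/n1 + 1/n2)) )`
#'
#' where `Yb`, `Yh` are the group means of the log values and `sigma_w` is
#' the within-group (ANOVA mean-square-error) standard deviation on the log
#' scale. Equivalence is declared when the CI falls strictly inside the
#' `limits` (default 0.70-1.43). The `sqrt(1/2)` factor is the
#' within-subject (crossover-style) standard error of the published
#' formula; `se = "textbook"` drops it, giving the standard parallel-group
#' two-sample standard error.
#'
#' @param candidate,original Per-animal enzyme activities (U/L, > 0) of the
#'   marker-combination group and the whole-extract group; both n >= 2.
#' @param alpha Nominal level: the CI has confidence `1 - alpha` (default
#'   0.10, i.e. a 90% CI built from the 0.95 t quantile).
#' @param limits Equivalence limits as fractions, default `c(0.70, 1.43)`.
#' @param se `"published"` (default; includes the 1/2 inside the root) or
#'   `"textbook"`.
#' @param groups Optional list of additional per-animal groups; when
#'   supplied, `sigma_w` is pooled across all groups by one-way ANOVA
#'   instead of the two compared groups only.
#' @return Object of class `equivalence_test`: `ratio` (geometric-mean
#'   ratio), `ratio_ci`, `sigma_w`, `df`, `t_quantile`, `limits`, `alpha`,
#'   `equivalent`.
#' @export
equivalence_test <- function(candidate, original, alpha = 0.10,
                             limits = c(0.70, 1.43),
                             se = c("published", "textbook"), groups = NULL) {
  se <- match.arg(se)
  stopifnot(length(candidate) >= 2, length(original) >= 2,
            all(candidate > 0), all(original > 0),
            length(limits) == 2, limits[1] < limits[2], alpha > 0, alpha < 0.5)
  n1 <- length(candidate); n2 <- length(original)
  lb <- log(candidate); lh <- log(original)
  all_groups <- c(list(lb, lh),
                  lapply(groups, function(g) { stopifnot(all(g > 0)); log(g) }))
  ss_w <- sum(vapply(all_groups, function(g) sum((g - mean(g))^2), 0))
  df_w <- sum(lengths(all_groups)) - length(all_groups)
  if (df_w < 1) stop("no within-group degrees of freedom")
  sigma_w <- sqrt(ss_w / df_w)
  df <- n1 + n2 - 2L
  tq <- stats::qt(1 - alpha / 2, df)
  half_factor <- if (se == "published") 0.5 else 1
  hw <- tq * sigma_w * sqrt(half_factor * (1 / n1 + 1 / n2))
  delta <- mean(lb) - mean(lh)
  ci <- exp(c(delta - hw, delta + hw))
  structure(list(ratio = exp(delta), ratio_ci = ci, sigma_w = sigma_w,
                 df = df, df_sigma = df_w, t_quantile = tq, limits = limits,
                 alpha = alpha, se = se, n1 = n1, n2 = n2,
                 equivalent = equivalence_decision(ci, limits)$equivalent),
            class = "equivalence_test")
}

#' Equivalence decision for a ratio confidence interval
#'
#' Declares equivalence if and only if the confidence interval lies
#' strictly inside the open limits interval (default `(0.70, 1.43)`).
#'
#' @param ci An `equivalence_test` object, or a length-2 numeric CI of the
#'   toxicity ratio (as fractions).
#' @param limits Equivalence limits, default `c(0.70, 1.43)`.
#' @return List with `equivalent` (logical) and `report` (the CI as
#'   percentages to 1 decimal, e.g. `"99.9-125.6%"`).
#' @export
equivalence_decision <- function(ci, limits = c(0.70, 1.43)) {
  if (inherits(ci, "equivalence_test")) {
    limits <- ci$limits
    ci <- ci$ratio_ci
  }
  stopifnot(length(ci) == 2, ci[1] <= ci[2])
  list(equivalent = ci[1] > limits[1] && ci[2] < limits[2],
       report = paste0(formatC(100 * ci[1], format = "f", digits = 1), "-",
                       formatC(100 * ci[2], format = "f", digits = 1), "%"))
}

#' @export
print.equivalence_test <- function(x, ...) {
  dec <- equivalence_decision(x)
  cat("Hepatotoxic equivalence (two one-sided t tests)\n")
  cat("  geometric-mean ratio:", formatC(x$ratio, format = "f", digits = 3),
      "\n")
  cat("  ", 100 * (1 - x$alpha), "% CI: ", dec$report,
      "  [limits ", 100 * x$limits[1], "-", 100 * x$limits[2], "%]\n",
      sep = "")
  cat("  sigma_w =", formatC(x$sigma_w, format = "f", digits = 4),
      "(log scale, df =", x$df_sigma, "), t =",
      formatC(x$t_quantile, format = "f", digits = 4), "\n")
  cat("  decision:", if (x$equivalent) "EQUIVALENT" else "not equivalent",
      "\n")
  invisible(x)
}

#' Packaged marker calibration and content table
#'
#' Calibration parameters (slope, intercept, tested range, R^2, LOD, LOQ)
#' for the two diterpenoid-lactone markers DIOB (diosbulbin B) and EEA
#' (8-epidiosbulbin E acetate), with their contents (%) in the three
#' verification extract batches S22-S24, as printed in the source table.
#'
#' @return List of two [calibration_curve()] objects (`DIOB`, `EEA`), each
#'   with a `contents` attribute (named fractions for S22-S24).
#' @export
dbt_calibration <- function() {
  path <- system.file("extdata", "dbt_calibration.csv",
                      package = "hecmscreen", mustWork = TRUE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(d)), function(i) {
    cc <- calibration_curve(
      slope = d$slope[i], intercept = d$intercept[i],
      range = c(d$range_low_ugml[i], d$range_high_ugml[i]),
      r2 = d$r2[i], lod = d$lod_ugml[i], loq = d$loq_ugml[i],
      analyte = d$analyte[i])
    attr(cc, "contents") <- c(S22 = d$content_pct_s22[i],
                              S23 = d$content_pct_s23[i],
                              S24 = d$content_pct_s24[i]) / 100
    cc
  })
  names(out) <- d$analyte
  out
}
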