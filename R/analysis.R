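# measures examined against symptoms / diagnosis: 18 motion + 2 fear codes
all_measures <- function(cohort) {
  c(intersect(feature_columns(), names(cohort)),
    intersect(c("fear_pt", "fear_at"), names(cohort)))
}

measure_parts <- function(v) {
  if (v %in% c("fear_pt", "fear_at"))
    return(c("fear", toupper(sub("^fear_", "", v))))
  c(sub("_(pt|s|rm)$", "", v), toupper(sub("^.*_(pt|s|rm)$", "\\1", v)))
}

#' Paired t tests of each measure across phase pairs
#'
#' For every motion variable, paired t tests across the three phase
#' pairs PT-S, S-RM and PT-RM, with differences taken first-listed
#' minus second-listed phase (so a variable that rises from Potential
#' Threat to Startle yields a negative PT-S t). The behavioral fear code
#' is compared Potential Threat vs Acute Threat. Two-sided p values.
#'
#' @param cohort A `fear_cohort` (or a cohort table, cleaned on the fly).
#' @return Data frame: variable, comparison, n, mean_diff, t, p.
#' @export
paired_phase_tests <- function(cohort) {
  fc <- as_fear_cohort(cohort)
  d <- fc$data
  pairs <- list(c("pt", "s"), c("s", "rm"), c("pt", "rm"))
  rows <- list()
  add <- function(variable, comparison, x, y) {
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 3)
      stop("paired test needs >= 3 complete pairs for ", variable)
    if (sd(x - y) == 0)
      stop("paired test undefined for ", variable,
           " (", comparison, "): zero-variance differences")
    tt <- t.test(x, y, paired = TRUE)
    data.frame(variable = variable, comparison = comparison,
               n = length(x), mean_diff = mean(x - y),
               t = unname(tt$statistic), p = tt$p.value,
               stringsAsFactors = FALSE)
  }
  for (v in motion_variables()) {
    for (pp in pairs) {
      c1 <- paste(v, pp[1], sep = "_"); c2 <- paste(v, pp[2], sep = "_")
      if (!all(c(c1, c2) %in% names(d))) next
      rows[[length(rows) + 1L]] <-
        add(v, paste(toupper(pp[1]), toupper(pp[2]), sep = "-"),
            d[[c1]], d[[c2]])
    }
  }
  if (all(c("fear_pt", "fear_at") %in% names(d)) &&
      any(is.finite(d$fear_pt) & is.finite(d$fear_at)))
    rows[[length(rows) + 1L]] <- add("fear", "PT-AT", d$fear_pt, d$fear_at)
  do.call(rbind, rows)
}

pearson_row <- function(x, y, min_n = 3) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < min_n)
    stop("correlation needs at least ", min_n, " complete pairs")
  if (sd(x) == 0 || sd(y) == 0)
    stop("correlation undefined: constant vector")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Correlations between IMU motion variables and behavioral fear codes
#'
#' Pearson correlations of each motion variable with the behavioral fear
#' code concurrent with its phase: Potential Threat motion against the
#' Potential Threat code; Startle and Response Modulation motion against
#' the Acute Threat code. Pairwise-complete deletion; two-sided p.
#'
#' @param cohort A `fear_cohort` or cohort table.
#' @return Data frame: variable, phase, code_phase, n, r, p.
#' @export
correlate_modalities <- function(cohort) {
  fc <- as_fear_cohort(cohort)
  d <- fc$data
  rows <- list()
  for (v in motion_variables()) {
    for (ph in phase_labels()) {
      col <- paste(v, ph, sep = "_")
      code_col <- if (ph == "pt") "fear_pt" else "fear_at"
      if (!all(c(col, code_col) %in% names(d))) next
      pr <- pearson_row(d[[col]], d[[code_col]])
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, phase = toupper(ph),
        code_phase = if (ph == "pt") "PotentialThreat" else "AcuteThreat",
        n = pr$n, r = pr$r, p = pr$p, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Correlations with parent-reported symptoms, plus a covariate screen
#'
#' Pearson correlations of every measure (each motion variable per phase
#' and the two behavioral fear codes) with the CBCL Internalizing and
#' Externalizing T scores, and a Spearman screen of every measure
#' against child age and gender (gender entered as integer codes of its
#' levels).
#'
#' @param cohort A `fear_cohort` or cohort table with `cbcl_internalizing`,
#'   `cbcl_externalizing`, `age`, `gender` columns.
#' @return A list with `symptoms` (variable, phase, scale, n, r, p) and
#'   `covariates` (variable, phase, covariate, n, rho, p).
#' @export
correlate_symptoms <- function(cohort) {
  fc <- as_fear_cohort(cohort)
  d <- fc$data
  sym_rows <- list()
  cov_rows <- list()
  gender_num <- if ("gender" %in% names(d))
    as.numeric(factor(d$gender)) - 1 else NULL
  for (v in all_measures(d)) {
    parts <- measure_parts(v)
    for (scale in c("cbcl_internalizing", "cbcl_externalizing")) {
      if (!scale %in% names(d)) next
      pr <- pearson_row(d[[v]], d[[scale]])
      sym_rows[[length(sym_rows) + 1L]] <- data.frame(
        variable = parts[1], phase = parts[2],
        scale = sub("cbcl_", "", scale),
        n = pr$n, r = pr$r, p = pr$p, stringsAsFactors = FALSE)
    }
    for (cov in c("age", "gender")) {
      y <- if (cov == "gender") gender_num else d[[cov]]
      if (is.null(y)) next
      ok <- is.finite(d[[v]]) & is.finite(y)
      if (sum(ok) < 3) next
      if (sd(y[ok]) == 0 || sd(d[[v]][ok]) == 0) {
        rho <- 0; p <- 1
      } else {
        ct <- suppressWarnings(
          cor.test(d[[v]][ok], y[ok], method = "spearman", exact = FALSE))
        rho <- unname(ct$estimate); p <- ct$p.value
      }
      cov_rows[[length(cov_rows) + 1L]] <- data.frame(
        variable = parts[1], phase = parts[2], covariate = cov,
        n = sum(ok), rho = rho, p = p, stringsAsFactors = FALSE)
    }
  }
  list(symptoms = do.call(rbind, sym_rows),
       covariates = do.call(rbind, cov_rows))
}

#' Compare measures between diagnosis groups
#'
#' Independent-samples t test (pooled variance) for every measure
#' between subjects without a history of internalizing diagnosis and
#' those with one (past or current), t computed as the no-diagnosis
#' group mean minus the diagnosis group mean (so elevated motion in
#' diagnosed children yields a negative t). Cohen's d with the pooled
#' standard deviation is reported for every row (positive when the
#' diagnosis group is higher), flagged significant at p < .05 and trend
#' at p < .10. An optional sensitivity rerun drops subjects with an
#' externalizing disorder.
#'
#' @param cohort A `fear_cohort` or cohort table with `internalizing_dx`
#'   (none/past/current) and, for the sensitivity rerun,
#'   `externalizing_dx`.
#' @param exclude_externalizing Drop subjects with `externalizing_dx`?
#' @return Data frame: variable, phase, n_none, n_dx, t, p, cohen_d,
#'   significance.
#' @export
compare_diagnosis_groups <- function(cohort, exclude_externalizing = FALSE) {
  fc <- as_fear_cohort(cohort)
  d <- fc$data
  if (!"internalizing_dx" %in% names(d))
    stop("cohort has no internalizing_dx column")
  d <- d[!is.na(d$internalizing_dx), , drop = FALSE]
  if (exclude_externalizing)
    d <- d[!is.na(d$externalizing_dx) & !d$externalizing_dx, , drop = FALSE]
  grp_dx <- d$internalizing_dx %in% c("past", "current")
  rows <- list()
  for (v in all_measures(d)) {
    x0 <- d[[v]][!grp_dx]; x1 <- d[[v]][grp_dx]
    x0 <- x0[is.finite(x0)]; x1 <- x1[is.finite(x1)]
    if (length(x0) < 2 || length(x1) < 2)
      stop("diagnosis comparison needs >= 2 subjects per group for ", v)
    tt <- t.test(x0, x1, var.equal = TRUE)
    sp <- sqrt(((length(x0) - 1) * var(x0) + (length(x1) - 1) * var(x1)) /
                 (length(x0) + length(x1) - 2))
    dval <- (mean(x1) - mean(x0)) / sp
    parts <- measure_parts(v)
    rows[[length(rows) + 1L]] <- data.frame(
      variable = parts[1], phase = parts[2],
      n_none = length(x0), n_dx = length(x1),
      t = unname(tt$statistic), p = tt$p.value, cohen_d = dval,
      significance = if (tt$p.value < 0.05) "sig"
                     else if (tt$p.value < 0.10) "trend" else "ns",
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Descriptive statistics of the cleaned variables
#'
#' Range, mean and sample standard deviation (n - 1 denominator) of each
#' measure per phase, computed on the winsorized (descriptive) scale ---
#' i.e. in the measurement units, before any log transform --- together
#' with the cleaning provenance flags.
#'
#' @param cohort A `fear_cohort` or cohort table.
#' @return Data frame: variable, phase, n, min, max, mean, sd,
#'   winsorized, log_transformed.
#' @export
describe_variables <- function(cohort) {
  fc <- as_fear_cohort(cohort)
  d <- fc$descriptive
  prov <- fc$provenance
  rows <- lapply(all_measures(d), function(v) {
    x <- d[[v]][is.finite(d[[v]])]
    parts <- measure_parts(v)
    pr <- prov[prov$variable == v, , drop = FALSE]
    data.frame(variable = parts[1], phase = parts[2], n = length(x),
               min = min(x), max = max(x), mean = mean(x), sd = sd(x),
               winsorized = if (nrow(pr)) pr$winsorized else FALSE,
               log_transformed = if (nrow(pr)) pr$log_transformed else FALSE,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the full statistical battery on a cohort
#'
#' Bundles the descriptives, paired phase contrasts, modality
#' correlations, symptom correlations with covariate screen, and
#' diagnosis-group comparisons (with the externalizing-exclusion
#' sensitivity rerun when the column is available) into one report.
#'
#' @param cohort A `fear_cohort` or cohort table.
#' @param sensitivity Also run the diagnosis comparison excluding
#'   subjects with externalizing disorders?
#' @return A list of result tables, class `fear_analysis`.
#' @export
analyze_cohort <- function(cohort, sensitivity = TRUE) {
  fc <- as_fear_cohort(cohort)
  have_meta <- all(c("cbcl_internalizing", "cbcl_externalizing")
                   %in% names(fc$data))
  have_dx <- "internalizing_dx" %in% names(fc$data) &&
    any(!is.na(fc$data$internalizing_dx))
  res <- list(
    descriptives = describe_variables(fc),
    phase_tests = paired_phase_tests(fc),
    modality_correlations = if (any(is.finite(fc$data$fear_at %||% NA)))
      correlate_modalities(fc) else NULL,
    symptom_correlations = if (have_meta) correlate_symptoms(fc) else NULL,
    diagnosis_tests = if (have_dx) compare_diagnosis_groups(fc) else NULL,
    diagnosis_tests_sensitivity =
      if (have_dx && sensitivity && "externalizing_dx" %in% names(fc$data))
        compare_diagnosis_groups(fc, exclude_externalizing = TRUE) else NULL,
    provenance = fc$provenance,
    n_subjects = nrow(fc$data)
  )
  class(res) <- "fear_analysis"
  res
}

#' @export
print.fear_analysis <- function(x, ...) {
  cat("<fear_analysis> cohort of", x$n_subjects, "subjects\n")
  cat("\nPhase contrasts (paired t):\n")
  print(x$phase_tests, digits = 3)
  if (!is.null(x$diagnosis_tests)) {
    cat("\nDiagnosis-group comparisons:\n")
    print(x$diagnosis_tests, digits = 3)
  }
  invisible(x)
}

#' Thin regression wrapper over the cohort table
#'
#' Convenience generic fit of a linear or logistic model on the
#' analysis-scale cohort data, for exploratory follow-up of the
#' univariate battery.
#'
#' @param cohort A `fear_cohort` or cohort table.
#' @param formula Model formula over cohort columns (an
#'   `internalizing_dx_flag` logical column is made available).
#' @param family A [stats::family] object; `gaussian()` by default,
#'   `binomial()` for logistic fits.
#' @return The fitted [stats::glm] object.
#' @export
fit_outcome <- function(cohort, formula, family = gaussian()) {
  fc <- as_fear_cohort(cohort)
  d <- fc$data
  if ("internalizing_dx" %in% names(d))
    d$internalizing_dx_flag <- d$internalizing_dx %in% c("past", "current")
  glm(formula, data = d, family = family)
}
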