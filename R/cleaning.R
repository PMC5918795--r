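sample_skewness <- function(x) e1071::skewness(x, na.rm = TRUE, type = 2)

# excess kurtosis (normal = 0), SPSS-style bias-corrected estimator
sample_kurtosis <- function(x) e1071::kurtosis(x, na.rm = TRUE, type = 2)

#' Clean one variable: conditional winsorizing and log transform
#'
#' Applies the screening rule used for all motion variables: if the
#' sample skewness exceeds `skew_threshold` (default 1) and/or the
#' kurtosis exceeds `kurt_threshold` (default 3, on the excess scale so
#' a normal distribution scores 0), the variable is winsorized at
#' approximately 5% --- values below the 5th empirical percentile are
#' clamped to the 5th percentile and values above the 95th to the 95th
#' (linear-interpolation percentile definition). If skewness or kurtosis
#' still exceeds the thresholds afterwards, a natural-log transform is
#' applied (requires a strictly positive minimum; variables that may be
#' zero, such as behavioral scores, set `allow_log = FALSE` and stay on
#' the winsorized scale). The function is idempotent: cleaning its own
#' output changes nothing once the thresholds are no longer tripped.
#'
#' @param x Numeric vector, at least 8 non-missing values.
#' @param winsor_fraction Tail fraction clamped on each side (0.05).
#' @param skew_threshold,kurt_threshold Trip thresholds.
#' @param kurtosis `"excess"` (default; normal = 0) or `"raw"`
#'   (normal = 3) scale for the kurtosis threshold.
#' @param allow_log Escalate to a log transform when winsorizing is not
#'   enough?
#' @param quantile_type Percentile definition passed to
#'   [stats::quantile()] (default 7, linear interpolation).
#' @param name Variable name used in error messages.
#' @return A list: `values` (analysis scale, log-transformed when
#'   flagged), `winsorized_values` (descriptive scale, clamped but never
#'   logged), flags `winsorized` and `log_transformed`, and the final
#'   `skewness` / `kurtosis_excess` of the analysis-scale values.
#' @export
#' @examples
#' x <- exp(rnorm(60))
#' cl <- clean_variable(x)
#' c(cl$winsorized, cl$log_transformed)
clean_variable <- function(x, winsor_fraction = 0.05, skew_threshold = 1,
                           kurt_threshold = 3,
                           kurtosis = c("excess", "raw"),
                           allow_log = TRUE, quantile_type = 7,
                           name = deparse(substitute(x))) {
  kurtosis <- match.arg(kurtosis)
  ok <- !is.na(x)
  if (sum(ok) < 8)
    stop("clean_variable needs at least 8 non-missing values for '", name, "'")
  kfun <- function(v) {
    k <- sample_kurtosis(v)
    if (kurtosis == "raw") k + 3 else k
  }
  # NaN moments (constant input) never trip the rule
  tripped <- function(v) {
    isTRUE(sample_skewness(v) > skew_threshold) ||
      isTRUE(kfun(v) > kurt_threshold)
  }
  out <- x
  wins <- FALSE
  logt <- FALSE
  if (tripped(x[ok])) {
    q <- quantile(x[ok], c(winsor_fraction, 1 - winsor_fraction),
                  type = quantile_type, names = FALSE)
    out <- pmin(pmax(x, q[1]), q[2])
    wins <- TRUE
    if (tripped(out[ok]) && allow_log) {
      if (min(out[ok]) <= 0)
        stop("log transform required for '", name,
             "' but its minimum is <= 0")
      logt <- TRUE
    }
  }
  values <- if (logt) log(out) else out
  list(values = values, winsorized_values = out,
       winsorized = wins, log_transformed = logt,
       skewness = sample_skewness(values[ok]),
       kurtosis_excess = sample_kurtosis(values[ok]))
}

#' Assemble the per-subject cohort table
#'
#' Joins the wide motion-feature table, the nonverbal behavioral fear
#' scores (Potential Threat and Acute Threat) and the subject metadata
#' into one row per subject. Subjects with features but without codes or
#' metadata keep NA in those columns (pairwise-complete deletion happens
#' inside each statistical comparison).
#'
#' @param features Wide feature table from [compute_cohort_features()]
#'   or [read_feature_table()].
#' @param scores Output of [score_fear_events()] (optional).
#' @param meta Output of [read_subject_meta()] (optional).
#' @return Data frame, one row per subject, class `cohort_table`.
#' @export
build_cohort_table <- function(features, scores = NULL, meta = NULL) {
  stopifnot(is.data.frame(features), "subject_id" %in% names(features))
  if (anyDuplicated(features$subject_id))
    stop("duplicate subject_id in feature table")
  out <- features
  if (!is.null(scores) && nrow(scores)) {
    fear <- nonverbal_fear_scores(scores)
    out <- merge(out, fear, by = "subject_id", all.x = TRUE, sort = TRUE)
  } else {
    out$fear_pt <- NA_real_
    out$fear_at <- NA_real_
  }
  if (!is.null(meta) && nrow(meta))
    out <- merge(out, meta, by = "subject_id", all.x = TRUE, sort = TRUE)
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Apply the cleaning rule across a cohort table
#'
#' Cleans the 18 motion variables (log escalation allowed) and the two
#' behavioral fear scores (winsorize only; scores can be zero) with
#' [clean_variable()], keeping both scales: the winsorized (descriptive)
#' scale feeds [describe_variables()], the analysis scale feeds every
#' statistical test, mirroring the convention of reporting descriptives
#' before transformation and testing after.
#'
#' The log decision is harmonized within each motion variable across its
#' three phases: if any phase escalates to the log scale, all phases of
#' that variable are logged, so that paired phase contrasts never mix
#' measurement scales. Winsorization stays per column.
#'
#' @param cohort A [build_cohort_table()] data frame.
#' @param ... Passed on to [clean_variable()] (thresholds, kurtosis
#'   scale, percentile type).
#' @return An object of class `fear_cohort`: `data` (analysis scale),
#'   `descriptive` (winsorized scale) and `provenance` (per-variable
#'   flags; `log_harmonized` marks phases logged only for scale
#'   consistency).
#' @export
clean_cohort <- function(cohort, ...) {
  stopifnot(is.data.frame(cohort))
  motion <- intersect(feature_columns(), names(cohort))
  codes <- intersect(c("fear_pt", "fear_at"), names(cohort))
  data <- as.data.frame(cohort)
  descr <- as.data.frame(cohort)
  cleaned <- list()
  for (v in c(motion, codes)) {
    if (all(is.na(cohort[[v]]))) next
    cleaned[[v]] <- clean_variable(cohort[[v]], allow_log = v %in% motion,
                                   name = v, ...)
  }
  # harmonize the log decision within each variable family across phases
  harmonized <- character(0)
  fams <- unique(sub("_(pt|s|rm)$", "", motion))
  for (fam in fams) {
    cols <- intersect(paste(fam, phase_labels(), sep = "_"), names(cleaned))
    if (any(vapply(cleaned[cols], `[[`, TRUE, "log_transformed"))) {
      for (v in cols) {
        if (cleaned[[v]]$log_transformed) next
        wv <- cleaned[[v]]$winsorized_values
        if (min(wv, na.rm = TRUE) <= 0)
          stop("log transform required for '", v,
               "' (phase harmonization) but its minimum is <= 0")
        cleaned[[v]]$values <- log(wv)
        cleaned[[v]]$log_transformed <- TRUE
        harmonized <- c(harmonized, v)
      }
    }
  }
  prov <- list()
  for (v in names(cleaned)) {
    cl <- cleaned[[v]]
    data[[v]] <- cl$values
    descr[[v]] <- cl$winsorized_values
    prov[[length(prov) + 1L]] <- data.frame(
      variable = v, winsorized = cl$winsorized,
      log_transformed = cl$log_transformed,
      log_harmonized = v %in% harmonized,
      skewness = sample_skewness(cl$values),
      kurtosis_excess = sample_kurtosis(cl$values),
      stringsAsFactors = FALSE)
  }
  structure(
    list(data = data, descriptive = descr,
         provenance = do.call(rbind, prov)),
    class = "fear_cohort"
  )
}

as_fear_cohort <- function(x, ...) {
  if (inherits(x, "fear_cohort")) x else clean_cohort(x, ...)
}

#' @export
print.fear_cohort <- function(x, ...) {
  cat(sprintf("<fear_cohort> %d subjects; %d cleaned variables (%d winsorized, %d log-transformed)\n",
              nrow(x$data), nrow(x$provenance),
              sum(x$provenance$winsorized), sum(x$provenance$log_transformed)))
  invisible(x)
}
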