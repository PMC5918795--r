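#' Intensity-weighted behavioral fear scores
#'
#' Scores coded behavior events per subject, phase, valence and channel:
#' each event contributes its interval duration weighted by intensity
#' (x1 low, x2 moderate, x3 high), and contributions are summed into one
#' score per (subject, phase, valence, channel). Groups with no events
#' score 0 for any subject that appears elsewhere in the event log, so
#' the output grid is complete over subjects x phases x valences x
#' channels. An alternative unweighted-by-duration reading (counting
#' weighted intervals) is available via `method = "count"`.
#'
#' @param events Validated event data frame (see [read_code_events()]).
#' @param weights Named intensity weights; default `c(low = 1,
#'   moderate = 2, high = 3)`.
#' @param method `"duration"` (default; weight x interval duration) or
#'   `"count"` (weight per interval, ignoring duration).
#' @return Data frame with columns `subject_id`, `phase`, `valence`,
#'   `channel`, `score` (nonnegative weighted seconds).
#' @export
#' @examples
#' ev <- data.frame(subject_id = "S1", phase = "AcuteThreat",
#'                  valence = "fear", channel = "nonverbal",
#'                  intensity = "high", duration = 2)
#' score_fear_events(ev)  # 3 x 2 = 6 weighted seconds
score_fear_events <- function(events,
                              weights = c(low = 1, moderate = 2, high = 3),
                              method = c("duration", "count")) {
  method <- match.arg(method)
  events <- validate_code_events(events)
  lv <- code_enum_levels()
  w <- weights[events$intensity]
  contrib <- if (method == "duration") w * events$duration else w
  tab <- tapply(contrib,
                list(subject_id = factor(events$subject_id),
                     phase = factor(events$phase, levels = lv$phase),
                     valence = factor(events$valence, levels = lv$valence),
                     channel = factor(events$channel, levels = lv$channel)),
                sum, default = 0)
  out <- as.data.frame.table(tab, responseName = "score",
                             stringsAsFactors = FALSE)
  out <- out[order(out$subject_id, out$phase, out$valence, out$channel), ]
  rownames(out) <- NULL
  out
}

# wide nonverbal-fear scores: one row per subject, fear_pt / fear_at
nonverbal_fear_scores <- function(scores) {
  sel <- scores[scores$valence == "fear" & scores$channel == "nonverbal", ]
  ids <- unique(sel$subject_id)
  data.frame(
    subject_id = ids,
    fear_pt = sel$score[match(paste(ids, "PotentialThreat"),
                              paste(sel$subject_id, sel$phase))],
    fear_at = sel$score[match(paste(ids, "AcuteThreat"),
                              paste(sel$subject_id, sel$phase))],
    stringsAsFactors = FALSE
  )
}

#' Inter-rater reliability: ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measure intraclass
#' correlation between two coders rating the same subjects, computed
#' from the classical ANOVA mean squares:
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)` with k = 2
#' raters, MSR the between-subject, MSC the between-rater and MSE the
#' residual mean square.
#'
#' @param scores_a,scores_b Equal-length paired score vectors (n >= 3),
#'   one per coder.
#' @return An object of class `icc_estimate`: the ICC value in
#'   \[-1, 1\] plus the underlying mean squares and sizes.
#' @export
#' @examples
#' a <- c(9, 6, 8, 7, 10, 6)
#' compute_icc(a, a)$icc  # perfect agreement: 1
compute_icc <- function(scores_a, scores_b) {
  if (length(scores_a) != length(scores_b))
    stop("paired score vectors must have equal length")
  ok <- is.finite(scores_a) & is.finite(scores_b)
  a <- scores_a[ok]
  b <- scores_b[ok]
  n <- length(a)
  if (n < 3) stop("ICC needs at least 3 paired ratings")
  y <- cbind(a, b)
  k <- 2L
  grand <- mean(y)
  ss_total <- sum((y - grand)^2)
  if (ss_total < 1e-12)
    stop("ICC undefined: total variance of ratings is zero")
  ss_rows <- k * sum((rowMeans(y) - grand)^2)
  ss_cols <- n * sum((colMeans(y) - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  structure(list(icc = icc, msr = msr, msc = msc, mse = mse, n = n, k = k),
            class = "icc_estimate")
}

#' @export
print.icc_estimate <- function(x, ...) {
  cat(sprintf("ICC(2,1) = %.3f  (n = %d subjects, k = %d raters)\n",
              x$icc, x$n, x$k))
  invisible(x)
}
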