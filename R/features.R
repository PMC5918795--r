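#' Segment a recording into the three temporal threat phases
#'
#' Anchors three contiguous, non-overlapping, half-open windows at the
#' startle instant: Potential Threat (PT) covering
#' `[t_startle - pre, t_startle - peri)`, Startle (S) covering
#' `[t_startle - peri, t_startle + peri)` and Response Modulation (RM)
#' covering `[t_startle + peri, t_startle + post)`. With the default
#' offsets (23, 3, 23 s) the durations are exactly 20, 6 and 20 s.
#' Sub-sample startle times are floored to the nearest sample boundary,
#' and a sample falling exactly on a window boundary is assigned to the
#' later window. At an exact sampling grid this yields a deterministic,
#' rate-independent sample count per window (2000/600/2000 at 100 Hz).
#'
#' @param t Sample-time vector (seconds), uniform grid.
#' @param t_startle Startle instant, seconds on the same clock.
#' @param sample_rate Hz; inferred from the median step when `NULL`.
#' @param offsets Named numeric vector `c(pre =, peri =, post =)` giving
#'   the window offsets in seconds before/around/after the startle.
#' @return An object of class `phase_windows`: the floored anchor time
#'   and a data frame of windows (phase, nominal start/end seconds, and
#'   sample index ranges).
#' @export
#' @examples
#' t <- seq(0, 60, by = 0.01)
#' segment_phases(t, 30)$windows
segment_phases <- function(t, t_startle, sample_rate = NULL,
                           offsets = c(pre = 23, peri = 3, post = 23)) {
  stopifnot(length(t) >= 2, all(c("pre", "peri", "post") %in% names(offsets)),
            all(offsets > 0), offsets["pre"] > offsets["peri"],
            offsets["post"] > offsets["peri"])
  fs <- sample_rate %||% (1 / median(diff(t)))
  i_s <- findInterval(t_startle + 1e-9, t)
  if (i_s < 1)
    stop("coverage error: startle time precedes the recording start")
  n_pre <- as.integer(round(offsets[["pre"]] * fs))
  n_peri <- as.integer(round(offsets[["peri"]] * fs))
  n_post <- as.integer(round(offsets[["post"]] * fs))
  i_s <- as.integer(i_s)
  i_pt <- c(i_s - n_pre, i_s - n_peri - 1L)
  i_st <- c(i_s - n_peri, i_s + n_peri - 1L)
  i_rm <- c(i_s + n_peri, i_s + n_post - 1L)
  if (i_pt[1] < 1)
    stop("coverage error: PotentialThreat window truncated (needs ",
         offsets[["pre"]], " s before the startle instant)")
  if (i_rm[2] > length(t))
    stop("coverage error: ResponseModulation window truncated (needs ",
         offsets[["post"]], " s after the startle instant)")
  anchor <- t[i_s]
  w <- data.frame(
    phase = c("PT", "S", "RM"),
    start_s = anchor + c(-offsets[["pre"]], -offsets[["peri"]], offsets[["peri"]]),
    end_s = anchor + c(-offsets[["peri"]], offsets[["peri"]], offsets[["post"]]),
    i_start = c(i_pt[1], i_st[1], i_rm[1]),
    i_end = c(i_pt[2], i_st[2], i_rm[2]),
    stringsAsFactors = FALSE
  )
  w$n_samples <- w$i_end - w$i_start + 1L
  structure(list(t_startle = t_startle, t_anchor = anchor,
                 sample_rate = fs, windows = w),
            class = "phase_windows")
}

#' @export
print.phase_windows <- function(x, ...) {
  cat(sprintf("<phase_windows> startle at %.3f s (anchor %.3f s)\n",
              x$t_startle, x$t_anchor))
  print(x$windows)
  invisible(x)
}

#' Compute the six per-phase motion summary measures
#'
#' For each phase window, computes the root-mean-square of the four
#' decomposed motion channels (`ah_rms`, `av_rms` in m/s^2; `wh_rms`,
#' `wv_rms` in deg/s) and the range of motion of the two orientation
#' angles (`alpha_rom`, `gamma_rom` in deg, max minus min), a total of
#' 18 values per subject. rms is taken on the per-sample planar/vertical
#' magnitudes, not per axis.
#'
#' @param dm [decompose_motion()] output.
#' @param orient [estimate_orientation()] output on the same time base.
#' @param windows [segment_phases()] output.
#' @param subject_id Subject identifier attached to the output row.
#' @return One-row data frame: `subject_id` plus `<variable>_<phase>`
#'   columns for variable in ah_rms, av_rms, wh_rms, wv_rms, alpha_rom,
#'   gamma_rom and phase in pt, s, rm.
#' @export
compute_phase_features <- function(dm, orient, windows,
                                   subject_id = "subject") {
  stopifnot(inherits(dm, "decomposed_motion"),
            inherits(orient, "orientation_trace"),
            inherits(windows, "phase_windows"))
  n <- length(dm$t)
  out <- data.frame(subject_id = as.character(subject_id),
                    stringsAsFactors = FALSE)
  for (k in seq_len(nrow(windows$windows))) {
    w <- windows$windows[k, ]
    if (w$i_start > w$i_end)
      stop("contract error: empty ", w$phase, " window")
    if (w$i_start < 1 || w$i_end > n)
      stop("contract error: ", w$phase, " window indices outside the signals")
    idx <- w$i_start:w$i_end
    ph <- tolower(w$phase)
    out[[paste0("ah_rms_", ph)]] <- rms(dm$a_h[idx])
    out[[paste0("av_rms_", ph)]] <- rms(dm$a_v[idx])
    out[[paste0("wh_rms_", ph)]] <- rms(dm$w_h[idx])
    out[[paste0("wv_rms_", ph)]] <- rms(dm$w_v[idx])
    out[[paste0("alpha_rom_", ph)]] <- rom(orient$alpha[idx])
    out[[paste0("gamma_rom_", ph)]] <- rom(orient$gamma[idx])
  }
  out[, c("subject_id", feature_columns())]
}

#' Extract per-phase motion features for a whole cohort
#'
#' Runs orientation estimation, motion decomposition, phase segmentation
#' and feature computation for every annotated recording. Subjects whose
#' startle annotation leaves a phase window uncovered (or that fail any
#' other contract) are excluded with a logged reason rather than
#' aborting the cohort.
#'
#' @param recordings List of [imu_recording()] objects.
#' @param annotations Data frame with `subject_id`, `t_startle` (seconds).
#' @param gain,up_axis,prefilter Passed to [estimate_orientation()].
#' @param offsets Passed to [segment_phases()].
#' @return A list with `features` (one row per retained subject),
#'   `exclusions` (subject_id, reason) and `phase_table` (per-subject
#'   phase boundaries in seconds, an auditable interval table).
#' @export
compute_cohort_features <- function(recordings, annotations, gain = 0.02,
                                    up_axis = "+z", prefilter = NULL,
                                    offsets = c(pre = 23, peri = 3, post = 23)) {
  ids <- vapply(recordings, function(r) r$subject_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate subject_id in recordings: ", ids[duplicated(ids)][1])
  rows <- list()
  excl <- list()
  phase_rows <- list()
  for (rec in recordings) {
    res <- tryCatch({
      ts <- annotations$t_startle[match(rec$subject_id, annotations$subject_id)]
      if (length(ts) == 0 || is.na(ts))
        stop("no startle annotation for subject ", rec$subject_id)
      orient <- estimate_orientation(rec, gain = gain, up_axis = up_axis,
                                     prefilter = prefilter)
      dm <- decompose_motion(rec, orient)
      w <- segment_phases(rec$t, ts, sample_rate = rec$sample_rate,
                          offsets = offsets)
      list(feat = compute_phase_features(dm, orient, w, rec$subject_id),
           phases = cbind(subject_id = rec$subject_id,
                          w$windows[, c("phase", "start_s", "end_s")]))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      excl[[length(excl) + 1L]] <- data.frame(
        subject_id = rec$subject_id, reason = conditionMessage(res),
        stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- res$feat
      phase_rows[[length(phase_rows) + 1L]] <- res$phases
    }
  }
  list(
    features = if (length(rows)) do.call(rbind, rows) else NULL,
    exclusions = if (length(excl)) do.call(rbind, excl) else
      data.frame(subject_id = character(0), reason = character(0)),
    phase_table = if (length(phase_rows)) do.call(rbind, phase_rows) else NULL
  )
}
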