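#' Simulation configuration for synthetic fear-task cohorts
#'
#' Defines the study conditions the simulator emulates: a waist-worn IMU
#' at 100 Hz over a ~52 s recording spanning all three threat phases,
#' torso motion modelled as band-limited random oscillations in tilt and
#' yaw plus translational sway with per-phase amplitudes, a startle
#' transient at the annotated instant, and a per-subject latent motion
#' factor that couples motion to the clinical metadata (diagnosis
#' effect, externalizing symptoms, behavioral fear codes). Per-phase
#' amplitude vectors are ordered (PT, S, RM); their defaults are
#' anchored so that simulated cohort descriptives fall inside
#' plausible published ranges for this task. All randomness uses R's
#' default Mersenne-Twister generator seeded from `seed`.
#'
#' @param n_subjects Cohort size.
#' @param seed Integer seed (`NULL` to use the current RNG state).
#' @param sample_rate Hz.
#' @param duration Recording length, seconds (>= 50).
#' @param startle_range Uniform range for the startle instant, seconds.
#' @param sway_h,sway_v Per-phase sway acceleration SD per axis, m/s^2
#'   (horizontal applies to each of the two horizontal world axes).
#' @param tilt_deg,tilt_fast_deg Per-phase tilt oscillation SDs, deg
#'   (slow wander and fast band).
#' @param yaw_deg,yaw_fast_deg Per-phase yaw oscillation SDs, deg.
#' @param sway_band,tilt_band,tilt_fast_band,yaw_band,yaw_fast_band
#'   Frequency bands in Hz for the oscillation banks.
#' @param n_osc Number of sinusoid components per bank.
#' @param mount_tilt_deg Baseline mounting tilt of the belt sensor, deg.
#' @param startle_peak Peak vertical acceleration of the startle
#'   transient, m/s^2.
#' @param startle_dur Startle transient duration, s.
#' @param noise_accel,noise_gyro White measurement noise SDs (m/s^2,
#'   deg/s).
#' @param subject_sigma SD of the per-subject latent log motion factor.
#' @param dx_effect_d Target standardized elevation of Potential Threat
#'   motion (log scale) in diagnosed subjects.
#' @param ext_corr_r Target correlation of the latent motion factor with
#'   the externalizing T score.
#' @param int_corr_r Weak coupling to the internalizing T score.
#' @param code_coupling_r Target correlation of the latent startle
#'   motion with the Acute Threat fear score.
#' @param dx_prevalence Fraction of subjects with an internalizing
#'   diagnosis (past or current).
#' @param past_fraction Fraction of diagnoses that are past rather than
#'   current.
#' @param fear_pt_mean,fear_pt_sd,fear_at_mean,fear_at_sd Behavioral
#'   fear score distribution parameters (weighted seconds).
#' @param n_uncoded Subjects without behavioral codes (uncodeable
#'   videos).
#' @param n_unassessed Subjects without diagnosis/CBCL data.
#' @param age_mean,age_sd,age_range,female_fraction Demographics.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 63,
                       seed = NULL,
                       sample_rate = 100,
                       duration = 52,
                       startle_range = c(25, 27),
                       sway_h = c(0.55, 1.00, 0.79),
                       sway_v = c(0.57, 0.75, 0.82),
                       tilt_deg = c(3.6, 2.0, 4.6),
                       tilt_fast_deg = c(0.45, 2.2, 0.65),
                       yaw_deg = c(14.5, 11.5, 15.0),
                       yaw_fast_deg = c(0.9, 2.8, 1.3),
                       sway_band = c(0.3, 2.0),
                       tilt_band = c(0.15, 1.0),
                       tilt_fast_band = c(1.4, 2.0),
                       yaw_band = c(0.05, 0.35),
                       yaw_fast_band = c(0.8, 2.0),
                       n_osc = 6,
                       mount_tilt_deg = 12,
                       startle_peak = 5,
                       startle_dur = 0.4,
                       noise_accel = 0.03,
                       noise_gyro = 0.3,
                       subject_sigma = 0.45,
                       dx_effect_d = 0.9,
                       ext_corr_r = 0.45,
                       int_corr_r = 0.10,
                       code_coupling_r = 0.5,
                       dx_prevalence = 21 / 61,
                       past_fraction = 4 / 21,
                       fear_pt_mean = 9.27, fear_pt_sd = 4.55,
                       fear_at_mean = 8.39, fear_at_sd = 5.05,
                       n_uncoded = 7,
                       n_unassessed = 2,
                       age_mean = 5.25, age_sd = 1.10,
                       age_range = c(3, 7),
                       female_fraction = 0.57) {
  cfg <- as.list(environment())
  amps <- c(cfg$sway_h, cfg$sway_v, cfg$tilt_deg, cfg$tilt_fast_deg,
            cfg$yaw_deg, cfg$yaw_fast_deg, cfg$startle_peak)
  stopifnot(all(amps >= 0), cfg$n_subjects >= 1, cfg$sample_rate > 0,
            cfg$duration >= 50,
            cfg$dx_prevalence > 0, cfg$dx_prevalence < 1)
  for (r in c(cfg$ext_corr_r, cfg$int_corr_r, cfg$code_coupling_r))
    if (abs(r) >= 1) stop("correlation targets must lie in (-1, 1)")
  # implied latent correlation structure must be positive definite
  rr <- c(cfg$ext_corr_r, cfg$int_corr_r, cfg$code_coupling_r)
  cm <- diag(4)
  cm[1, 2:4] <- cm[2:4, 1] <- rr
  cm[2, 3] <- cm[3, 2] <- rr[1] * rr[2]
  cm[2, 4] <- cm[4, 2] <- rr[1] * rr[3]
  cm[3, 4] <- cm[4, 3] <- rr[2] * rr[3]
  if (min(eigen(cm, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("config error: implied correlation matrix is not positive definite")
  stopifnot(length(cfg$startle_range) == 2,
            cfg$startle_range[1] >= 23,
            cfg$startle_range[2] <= cfg$duration - 23)
  class(cfg) <- "sim_config"
  cfg
}

# bank of n sinusoids over a frequency band with unit total SD
osc_bank <- function(n, band) {
  list(f = runif(n, band[1], band[2]),
       ph = runif(n, 0, 2 * pi),
       a = rep(sqrt(2 / n), n))
}

osc_eval <- function(b, t) {
  as.numeric(sin(outer(t, 2 * pi * b$f) +
                   matrix(b$ph, length(t), length(b$f), byrow = TRUE)) %*% b$a)
}

osc_deriv <- function(b, t) {
  as.numeric(cos(outer(t, 2 * pi * b$f) +
                   matrix(b$ph, length(t), length(b$f), byrow = TRUE)) %*%
               (b$a * 2 * pi * b$f))
}

# piecewise-constant per-phase level with raised-cosine transitions
envelope_eval <- function(t, bounds, levels, tau = 1) {
  e <- rep(levels[1], length(t))
  for (j in seq_along(bounds)) {
    lo <- bounds[j] - tau / 2
    hi <- bounds[j] + tau / 2
    e[t >= hi] <- levels[j + 1]
    sel <- t >= lo & t < hi
    e[sel] <- levels[j] + (levels[j + 1] - levels[j]) *
      (1 - cos(pi * (t[sel] - lo) / tau)) / 2
  }
  e
}

envelope_deriv <- function(t, bounds, levels, tau = 1) {
  de <- numeric(length(t))
  for (j in seq_along(bounds)) {
    lo <- bounds[j] - tau / 2
    sel <- t >= lo & t < lo + tau
    de[sel] <- (levels[j + 1] - levels[j]) * pi / (2 * tau) *
      sin(pi * (t[sel] - lo) / tau)
  }
  de
}

# exact forward kinematics: orientation = yaw about world z then tilt
# about body x; returns sensor-frame specific force and angular rate
forward_imu <- function(theta_deg, theta_dot_dps, psi_deg, psi_dot_dps,
                        a_world) {
  th <- rad(theta_deg)
  ct <- cos(th); st <- sin(th)
  ps <- rad(psi_deg)
  cp <- cos(ps); sp <- sin(ps)
  gyro <- cbind(theta_dot_dps, psi_dot_dps * st, psi_dot_dps * ct)
  fx <- a_world[, 1]; fy <- a_world[, 2]; fz <- a_world[, 3] + .g0
  v1x <- cp * fx + sp * fy
  v1y <- -sp * fx + cp * fy
  accel <- cbind(v1x, ct * v1y + st * fz, -st * v1y + ct * fz)
  list(accel = accel, gyro = gyro)
}

#' Analytically exact noise-free IMU fixtures
#'
#' Generates small reference recordings whose downstream features have
#' closed forms, for oracle testing: `static` (upright, no motion),
#' `tilted_static` (constant tilt), `constant_yaw_rotation` (pure
#' turning about the vertical), `tilt_sine` (sinusoidal leaning about a
#' nonzero mean tilt so the tilt angle never folds through zero) and
#' `sway_sine` (sinusoidal horizontal translation). Signals are
#' synthesized by exact forward kinematics with zero measurement noise.
#'
#' @param kind Fixture name (see above).
#' @param params Named list of parameters overriding the defaults:
#'   `duration`, `sample_rate` for all kinds; `tilt_deg`
#'   (tilted_static); `rate_dps` (constant_yaw_rotation); `amp_deg`,
#'   `freq_hz`, `mean_deg` (tilt_sine); `amp`, `freq_hz` (sway_sine).
#' @return An [imu_recording()].
#' @export
#' @examples
#' rec <- simulate_fixture("constant_yaw_rotation",
#'                         list(rate_dps = 20, duration = 5))
simulate_fixture <- function(kind, params = list()) {
  p <- function(name, default) params[[name]] %||% default
  fs <- p("sample_rate", 100)
  dur <- p("duration", 10)
  t <- seq(0, dur, by = 1 / fs)
  n <- length(t)
  zero <- numeric(n)
  aw0 <- matrix(0, n, 3)
  sig <- switch(
    kind,
    static = forward_imu(zero, zero, zero, zero, aw0),
    tilted_static = {
      th <- rep(p("tilt_deg", 30), n)
      forward_imu(th, zero, zero, zero, aw0)
    },
    constant_yaw_rotation = {
      rate <- p("rate_dps", 20)
      forward_imu(zero, zero, rate * t, rep(rate, n), aw0)
    },
    tilt_sine = {
      A <- p("amp_deg", 10)
      f <- p("freq_hz", 0.5)
      m <- p("mean_deg", max(30, A + 5))
      th <- m + A * sin(2 * pi * f * t)
      thd <- A * 2 * pi * f * cos(2 * pi * f * t)
      forward_imu(th, thd, zero, zero, aw0)
    },
    sway_sine = {
      A <- p("amp", 1)
      f <- p("freq_hz", 0.5)
      aw <- cbind(A * sin(2 * pi * f * t), zero, zero)
      forward_imu(zero, zero, zero, zero, aw)
    },
    stop("unknown fixture kind: ", kind)
  )
  imu_recording(paste0("fixture_", kind), t, sig$accel, sig$gyro,
                sample_rate = fs)
}

#' Simulate one subject's task recording
#'
#' Synthesizes a full-length waist IMU recording for one subject by
#' exact forward kinematics: band-limited random oscillations in tilt
#' and yaw (slow wander plus a fast band) and translational sway, with
#' per-phase amplitude envelopes (raised-cosine transitions at the phase
#' boundaries) scaled by the subject's phase multipliers, a vertical
#' startle transient at the startle instant, a constant mounting tilt,
#' and white measurement noise. Uses the current RNG state; seed the
#' generator (or use [simulate_cohort()]) for reproducibility.
#'
#' @param config A [sim_config()].
#' @param subject_id Identifier for the recording.
#' @param mult Named per-phase amplitude multipliers `c(pt =, s =, rm =)`.
#' @return A list: `recording` ([imu_recording()]), `t_startle`
#'   (seconds), and `truth` (the noiseless tilt/yaw trajectories).
#' @export
simulate_subject_motion <- function(config, subject_id = "S001",
                                    mult = c(pt = 1, s = 1, rm = 1)) {
  stopifnot(inherits(config, "sim_config"))
  fs <- config$sample_rate
  t <- seq(0, config$duration, by = 1 / fs)
  n <- length(t)
  ts <- runif(1, config$startle_range[1], config$startle_range[2])
  bounds <- c(ts - 3, ts + 3)
  lev <- function(base) base * unname(mult[c("pt", "s", "rm")])

  channel <- function(sd_phase, band) {
    b <- osc_bank(config$n_osc, band)
    e <- envelope_eval(t, bounds, lev(sd_phase))
    de <- envelope_deriv(t, bounds, lev(sd_phase))
    s <- osc_eval(b, t)
    ds <- osc_deriv(b, t)
    list(x = e * s, dx = de * s + e * ds)
  }

  tilt_slow <- channel(config$tilt_deg, config$tilt_band)
  tilt_fast <- channel(config$tilt_fast_deg, config$tilt_fast_band)
  yaw_slow <- channel(config$yaw_deg, config$yaw_band)
  yaw_fast <- channel(config$yaw_fast_deg, config$yaw_fast_band)

  theta <- config$mount_tilt_deg + tilt_slow$x + tilt_fast$x
  theta_dot <- tilt_slow$dx + tilt_fast$dx
  psi <- yaw_slow$x + yaw_fast$x
  psi_dot <- yaw_slow$dx + yaw_fast$dx

  ax <- channel(config$sway_h, config$sway_band)$x
  ay <- channel(config$sway_h, config$sway_band)$x
  az <- channel(config$sway_v, config$sway_band)$x
  # startle transient: vertical half-sine pulse at the startle instant
  pulse <- t >= ts & t < ts + config$startle_dur
  az[pulse] <- az[pulse] + config$startle_peak * unname(mult["s"]) *
    sin(pi * (t[pulse] - ts) / config$startle_dur)

  sig <- forward_imu(theta, theta_dot, psi, psi_dot, cbind(ax, ay, az))
  if (config$noise_accel > 0)
    sig$accel <- sig$accel + rnorm(3 * n, sd = config$noise_accel)
  if (config$noise_gyro > 0)
    sig$gyro <- sig$gyro + rnorm(3 * n, sd = config$noise_gyro)
  list(
    recording = imu_recording(subject_id, t, sig$accel, sig$gyro,
                              sample_rate = fs),
    t_startle = ts,
    truth = list(theta = theta, psi = psi)
  )
}

# latent subject-level variables and metadata with the configured
# coupling structure (Gaussian copula on a single latent motion factor)
simulate_metadata <- function(config, n = config$n_subjects) {
  z <- rnorm(n)
  dx_flag <- rbinom(n, 1, config$dx_prevalence) == 1
  dx <- rep("none", n)
  dx[dx_flag] <- ifelse(runif(sum(dx_flag)) < config$past_fraction,
                        "past", "current")
  ext_dx <- rbinom(n, 1, ifelse(dx_flag, 4 / 21, 1 / 40)) == 1
  re <- config$ext_corr_r
  ri <- config$int_corr_r
  clamp_t <- function(x) pmin(110, pmax(20, x))
  cbcl_ext <- clamp_t(round(50 + 10 * (re * z + sqrt(1 - re^2) * rnorm(n)), 1))
  cbcl_int <- clamp_t(round(50 + 10 * (ri * z + sqrt(1 - ri^2) * rnorm(n)) +
                              3 * dx_flag, 1))
  rc <- config$code_coupling_r
  fear_at <- pmax(0, config$fear_at_mean +
                    config$fear_at_sd * (rc * z + sqrt(1 - rc^2) * rnorm(n)))
  fear_pt <- pmax(0, config$fear_pt_mean + config$fear_pt_sd * rnorm(n))
  age <- pmin(config$age_range[2],
              pmax(config$age_range[1],
                   round(rnorm(n, config$age_mean, config$age_sd), 1)))
  gender <- ifelse(runif(n) < config$female_fraction, "female", "male")
  list(z = z, internalizing_dx = dx, externalizing_dx = ext_dx,
       cbcl_internalizing = cbcl_int, cbcl_externalizing = cbcl_ext,
       fear_pt = fear_pt, fear_at = fear_at, age = age, gender = gender)
}

# decompose a target weighted score into 1-3 coded events whose
# intensity-weighted durations sum exactly to the score
events_from_score <- function(subject_id, phase, score,
                              valence = "fear", channel = "nonverbal") {
  if (score <= 0) return(NULL)
  wmap <- c(low = 1, moderate = 2, high = 3)
  k <- sample(1:3, 1)
  p <- runif(k)
  p <- p / sum(p)
  intensity <- sample(names(wmap), k, replace = TRUE)
  data.frame(subject_id = subject_id, phase = phase, valence = valence,
             channel = channel, intensity = intensity,
             duration = score * p / wmap[intensity],
             stringsAsFactors = FALSE)
}

#' Simulate a complete synthetic cohort
#'
#' Generates the full file set the pipeline ingests: per-subject IMU
#' recordings with startle annotations, behavioral code-event logs, and
#' subject metadata. A per-subject latent motion factor drives (a) the
#' motion amplitude in every phase, elevated in Potential Threat for
#' diagnosed subjects by `dx_effect_d` standardized (log-scale) units,
#' (b) the externalizing T score via a Gaussian copula at
#' `ext_corr_r`, and (c) the Acute Threat fear score via noisy linear
#' coupling at `code_coupling_r`; the internalizing T score is weakly
#' coupled and age/gender are independent. A random subset of subjects
#' lacks behavioral codes (`n_uncoded`) and another lacks
#' diagnosis/CBCL data (`n_unassessed`), mirroring real attrition.
#'
#' @param config A [sim_config()]; its `seed` (when non-NULL) makes the
#'   cohort fully deterministic.
#' @param dir Optional directory; when given, all files are written
#'   there (`imu/<id>.csv`, `annotations.csv`, `events.csv`, `meta.csv`
#'   and a `manifest.json` listing paths and the config used).
#' @return A list: `recordings` (named list of [imu_recording()]),
#'   `annotations`, `events`, `meta` (data frames), `latent` (true
#'   subject-level factors) and `config`.
#' @export
simulate_cohort <- function(config = sim_config(), dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_subjects
  ids <- sprintf("S%03d", seq_len(n))
  lat <- simulate_metadata(config)
  dx_flag <- lat$internalizing_dx %in% c("past", "current")
  base_mult <- exp(config$subject_sigma * lat$z)
  pt_mult <- base_mult * exp(config$dx_effect_d * config$subject_sigma *
                               as.numeric(dx_flag))
  uncoded <- sample(ids, min(config$n_uncoded, n))
  unassessed <- sample(setdiff(ids, uncoded),
                       min(config$n_unassessed, n - length(uncoded)))

  recordings <- vector("list", n)
  names(recordings) <- ids
  ann <- data.frame(subject_id = ids, t_startle = NA_real_,
                    stringsAsFactors = FALSE)
  ev_list <- list()
  for (i in seq_len(n)) {
    sim <- simulate_subject_motion(
      config, ids[i],
      mult = c(pt = pt_mult[i], s = base_mult[i], rm = base_mult[i]))
    recordings[[i]] <- sim$recording
    ann$t_startle[i] <- sim$t_startle
    if (!(ids[i] %in% uncoded)) {
      ev_list[[length(ev_list) + 1L]] <- rbind(
        events_from_score(ids[i], "PotentialThreat", lat$fear_pt[i]),
        events_from_score(ids[i], "AcuteThreat", lat$fear_at[i]),
        # filler events in other valences keep every coded subject in the log
        events_from_score(ids[i], "PotentialThreat",
                          runif(1, 0.5, 3), valence = "positivity"))
    }
  }
  events <- if (length(ev_list)) do.call(rbind, ev_list) else
    data.frame(subject_id = character(0), phase = character(0),
               valence = character(0), channel = character(0),
               intensity = character(0), duration = numeric(0))
  rownames(events) <- NULL
  meta <- data.frame(
    subject_id = ids, age = lat$age, gender = lat$gender,
    cbcl_internalizing = lat$cbcl_internalizing,
    cbcl_externalizing = lat$cbcl_externalizing,
    internalizing_dx = lat$internalizing_dx,
    externalizing_dx = lat$externalizing_dx,
    stringsAsFactors = FALSE)
  drop <- meta$subject_id %in% unassessed
  meta$cbcl_internalizing[drop] <- NA
  meta$cbcl_externalizing[drop] <- NA
  meta$internalizing_dx[drop] <- NA
  meta$externalizing_dx[drop] <- NA

  out <- list(recordings = recordings, annotations = ann, events = events,
              meta = meta,
              latent = list(z = lat$z, dx_flag = dx_flag,
                            uncoded = uncoded, unassessed = unassessed),
              config = config)
  if (!is.null(dir)) write_cohort_files(out, dir)
  out
}

# write the cohort as the CSV dialects the readers ingest, plus manifest
write_cohort_files <- function(cohort, dir) {
  dir.create(file.path(dir, "imu"), recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  for (rec in cohort$recordings) {
    p <- file.path(dir, "imu", paste0(rec$subject_id, ".csv"))
    write_imu_csv(rec, p, overwrite = TRUE)
    paths$imu <- c(paths$imu, p)
  }
  paths$annotations <- file.path(dir, "annotations.csv")
  write_csv_full_precision(cohort$annotations, paths$annotations)
  paths$events <- file.path(dir, "events.csv")
  write_csv_full_precision(cohort$events, paths$events)
  paths$meta <- file.path(dir, "meta.csv")
  write_csv_full_precision(cohort$meta, paths$meta)
  cfg <- cohort$config
  class(cfg) <- NULL
  manifest <- list(paths = lapply(paths, as.character), config = cfg)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Simulate a second coder for reliability analysis
#'
#' Given one coder's scores, generates a pair of coder score vectors
#' with a configured expected intraclass correlation, by treating the
#' given scores as true subject levels and adding independent coder
#' noise with variance `var(scores) * (1 - icc) / icc` to each coder.
#'
#' @param scores Numeric score vector (one per subject).
#' @param icc Target ICC(2,1) in (0, 1).
#' @return Data frame with `coder_a`, `coder_b`.
#' @export
simulate_coder_pair <- function(scores, icc = 0.88) {
  stopifnot(icc > 0, icc < 1, length(scores) >= 3)
  s2 <- var(scores)
  sde <- sqrt(s2 * (1 - icc) / icc)
  data.frame(coder_a = scores + rnorm(length(scores), sd = sde),
             coder_b = scores + rnorm(length(scores), sd = sde))
}

#' Parameter-recovery study over repeated synthetic cohorts
#'
#' Repeatedly simulates a cohort, runs the full extraction pipeline
#' (orientation estimation, decomposition, segmentation, features,
#' behavioral scoring) and measures how well the configured effects are
#' recovered on the log scale, where the generator imposes them:
#' the diagnosis effect as Cohen's d of log Potential Threat `ah_rms`
#' (diagnosed minus not, pooled SD), the externalizing coupling as the
#' Pearson r of log Response Modulation `ah_rms` with the externalizing
#' T score, and the code coupling as the Pearson r of log Startle
#' `ah_rms` with the Acute Threat fear score.
#'
#' @param config A [sim_config()]; its `seed` field is overridden per
#'   replicate.
#' @param n_seeds Number of replicate cohorts.
#' @param base_seed Replicate i uses seed `base_seed + i`.
#' @return A list with `per_seed` (data frame of estimates) and `means`
#'   (named vector of the three mean estimates).
#' @export
recover_effects <- function(config = sim_config(n_subjects = 61,
                                                n_uncoded = 0,
                                                n_unassessed = 0),
                            n_seeds = 200, base_seed = 20000) {
  est <- data.frame(seed = integer(0), d_pt = numeric(0),
                    r_ext = numeric(0), r_code = numeric(0))
  for (i in seq_len(n_seeds)) {
    cfg <- config
    cfg$seed <- base_seed + i
    coh <- simulate_cohort(cfg)
    feats <- compute_cohort_features(coh$recordings, coh$annotations)$features
    scores <- score_fear_events(coh$events)
    tab <- build_cohort_table(feats, scores, coh$meta)
    dx <- tab$internalizing_dx %in% c("past", "current")
    keep <- !is.na(tab$internalizing_dx)
    x0 <- log(tab$ah_rms_pt[keep & !dx])
    x1 <- log(tab$ah_rms_pt[keep & dx])
    sp <- sqrt(((length(x0) - 1) * var(x0) + (length(x1) - 1) * var(x1)) /
                 (length(x0) + length(x1) - 2))
    d_pt <- (mean(x1) - mean(x0)) / sp
    r_ext <- cor(log(tab$ah_rms_rm), tab$cbcl_externalizing,
                 use = "pairwise.complete.obs")
    r_code <- cor(log(tab$ah_rms_s), tab$fear_at,
                  use = "pairwise.complete.obs")
    est[i, ] <- list(base_seed + i, d_pt, r_ext, r_code)
  }
  list(per_seed = est,
       means = c(d_pt = mean(est$d_pt), r_ext = mean(est$r_ext),
                 r_code = mean(est$r_code)))
}
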