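test_that("cohorts are bit-identical under a fixed seed", {
  cfg <- sim_config(n_subjects = 2, seed = 101)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$recordings[[1]]$accel, b$recordings[[1]]$accel)
  expect_identical(a$recordings[[2]]$gyro, b$recordings[[2]]$gyro)
  expect_identical(a$annotations, b$annotations)
  expect_identical(a$events, b$events)
  expect_identical(a$meta, b$meta)
})

test_that("zero amplitudes and noise yield a static recording", {
  set.seed(103)
  z3 <- c(0, 0, 0)
  cfg <- sim_config(sway_h = z3, sway_v = z3, tilt_deg = z3,
                    tilt_fast_deg = z3, yaw_deg = z3, yaw_fast_deg = z3,
                    noise_accel = 0, noise_gyro = 0, startle_peak = 0,
                    mount_tilt_deg = 12)
  sim <- simulate_subject_motion(cfg, "static")
  rec <- sim$recording
  expect_equal(max(abs(rec$gyro)), 0)
  o <- estimate_orientation(rec)
  expect_equal(o$alpha, rep(12, length(rec$t)), tolerance = 1e-9)
  dm <- decompose_motion(rec, o)
  w <- segment_phases(rec$t, sim$t_startle)
  f <- compute_phase_features(dm, o, w, "static")
  expect_true(all(abs(unlist(f[, -1])) < 1e-6))
})

test_that("fixture features match sinusoid closed forms end to end", {
  # tilt sinusoid amplitude A: alpha rom = 2A, gyro channel rms = A_rate/sqrt(2)
  for (A in c(5, 10)) {
    f_hz <- 0.5
    rec <- simulate_fixture("tilt_sine",
                            list(amp_deg = A, freq_hz = f_hz, duration = 20))
    o <- estimate_orientation(rec)
    dm <- decompose_motion(rec, o)
    expect_equal(rom(o$alpha), 2 * A, tolerance = 0.5 / (2 * A))
    a_rate <- 2 * pi * f_hz * A
    expect_equal(rms(dm$w_h), a_rate / sqrt(2), tolerance = 0.01)
  }
  # horizontal sway sinusoid: ah rms = A/sqrt(2) (gyro-dominant gain:
  # the accelerometer direction is not gravity during sustained sway and
  # this fixture's gyro is exact)
  rec <- simulate_fixture("sway_sine", list(amp = 1, freq_hz = 0.5,
                                            duration = 20))
  o <- estimate_orientation(rec, gain = 1e-6)
  dm <- decompose_motion(rec, o)
  expect_equal(rms(dm$a_h), 1 / sqrt(2), tolerance = 0.01)
  expect_lt(rms(dm$a_v), 0.05)
  expect_error(simulate_fixture("wiggle"), "unknown fixture kind")
})

test_that("generated metadata converges to the configured couplings", {
  set.seed(7)
  cfg <- sim_config(n_subjects = 5000)
  md <- fearmotion:::simulate_metadata(cfg)
  expect_lt(abs(cor(md$cbcl_externalizing, md$z) - cfg$ext_corr_r), 0.02)
  expect_lt(abs(cor(md$cbcl_internalizing, md$z) - cfg$int_corr_r), 0.02)
  expect_lt(abs(cor(md$fear_at, md$z) - cfg$code_coupling_r), 0.02)
  expect_true(all(md$cbcl_internalizing >= 20 & md$cbcl_internalizing <= 110))
  expect_true(all(md$age >= 3 & md$age <= 7))
})

test_that("cohort structure matches the configured design", {
  cfg <- sim_config(n_subjects = 63, seed = 107)
  coh <- simulate_cohort(cfg)
  expect_length(coh$recordings, 63)
  expect_equal(nrow(coh$meta), 63)
  n_dx <- sum(coh$meta$internalizing_dx %in% c("past", "current"))
  expect_gt(n_dx, 10)
  expect_lt(n_dx, 33)
  expect_equal(sum(is.na(coh$meta$internalizing_dx)), 2)
  # 7 uncoded subjects leave 56 in the event log
  expect_equal(length(unique(coh$events$subject_id)), 56)
  # annotations leave full phase coverage
  expect_true(all(coh$annotations$t_startle >= 23))
  expect_true(all(coh$annotations$t_startle <= cfg$duration - 23))
  # features extract without NaN for every subject
  f <- compute_cohort_features(coh$recordings, coh$annotations)$features
  expect_equal(nrow(f), 63)
  expect_false(anyNA(f))
  # simulated descriptives stay inside plausible published spans
  expect_gt(mean(f$ah_rms_pt), 0.32)
  expect_lt(mean(f$ah_rms_pt), 2.27)
})

test_that("a null diagnosis effect yields near-zero group differences", {
  ds <- numeric(3)
  for (i in 1:3) {
    cfg <- sim_config(n_subjects = 40, seed = 120 + i, dx_effect_d = 0,
                      n_uncoded = 0, n_unassessed = 0)
    coh <- simulate_cohort(cfg)
    f <- compute_cohort_features(coh$recordings, coh$annotations)$features
    tab <- build_cohort_table(f, score_fear_events(coh$events), coh$meta)
    dx <- tab$internalizing_dx %in% c("past", "current")
    x0 <- log(tab$ah_rms_pt[!dx]); x1 <- log(tab$ah_rms_pt[dx])
    sp <- sqrt(((length(x0) - 1) * var(x0) + (length(x1) - 1) * var(x1)) /
                 (length(x0) + length(x1) - 2))
    ds[i] <- (mean(x1) - mean(x0)) / sp
  }
  expect_lt(abs(mean(ds)), 0.35)
})

test_that("coder-pair simulation hits the reliability band", {
  set.seed(131)
  scores <- pmax(0, rnorm(200, 9, 4.5))
  pair <- simulate_coder_pair(scores, icc = 0.88)
  est <- compute_icc(pair$coder_a, pair$coder_b)
  expect_equal(est$icc, 0.88, tolerance = 0.06)
})

test_that("written cohort files are the dialect the readers ingest", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_subjects = 3, seed = 109, n_uncoded = 1,
                    n_unassessed = 1)
  coh <- simulate_cohort(cfg, dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  rec <- read_imu_csv(file.path(dir, "imu", "S001.csv"))
  expect_identical(unname(rec$accel), unname(coh$recordings$S001$accel))
  ann <- read_startle_annotations(file.path(dir, "annotations.csv"))
  expect_equal(ann$t_startle, coh$annotations$t_startle, tolerance = 0)
  ev <- read_code_events(file.path(dir, "events.csv"))
  sc <- score_fear_events(ev)
  expect_true(all(sc$score >= 0))
  meta <- read_subject_meta(file.path(dir, "meta.csv"))
  expect_equal(nrow(meta), 3)
})
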