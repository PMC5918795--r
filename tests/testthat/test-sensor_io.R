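test_that("read_imu_csv converts units and infers the sample rate", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(t = c(0, 0.01, 0.02), ax = 0, ay = 0, az = 1,
                   gx = 0, gy = 0, gz = pi / 2)
  write.csv(df, tmp, row.names = FALSE)
  rec <- read_imu_csv(tmp, imu_schema(accel_unit = "g", gyro_unit = "rps"))
  expect_equal(rec$accel[, 3], rep(9.80665, 3))
  expect_equal(rec$gyro[, 3], rep(90, 3))
  expect_equal(rec$sample_rate, 100)
})

test_that("reading canonical-unit data is unit-idempotent (round trip)", {
  set.seed(11)
  t <- seq(0, 2, by = 0.01)
  rec <- imu_recording("rt", t,
                       matrix(rnorm(3 * length(t)), ncol = 3),
                       matrix(rnorm(3 * length(t)), ncol = 3))
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_imu_csv(rec, tmp)
  back <- read_imu_csv(tmp, subject_id = "rt")
  expect_equal(back$t, rec$t, tolerance = 0)
  expect_equal(unname(back$accel), unname(rec$accel), tolerance = 0)
  expect_equal(unname(back$gyro), unname(rec$gyro), tolerance = 0)
  # a second write/read cycle changes nothing either
  tmp2 <- withr::local_tempfile(fileext = ".csv")
  write_imu_csv(back, tmp2)
  again <- read_imu_csv(tmp2, subject_id = "rt")
  expect_identical(unname(again$accel), unname(back$accel))
})

test_that("schema violations and disordered samples are rejected", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(t = c(0, 0.01), ax = 0, ay = 0, az = 9.8,
                   gx = 0, gy = 0)  # gz missing
  write.csv(df, tmp, row.names = FALSE)
  expect_error(read_imu_csv(tmp), "missing columns.*gz")

  df2 <- data.frame(t = c(0, 0.02, 0.01), ax = 0, ay = 0, az = 9.8,
                    gx = 0, gy = 0, gz = 0)
  write.csv(df2, tmp, row.names = FALSE)
  expect_error(read_imu_csv(tmp), "monotone")
})

test_that("short missing-sample gaps are interpolated, long ones fatal", {
  t <- seq(0, 0.99, by = 0.01)
  base <- data.frame(t = t, ax = sin(t), ay = 0, az = 9.8,
                     gx = 0, gy = 0, gz = 0)
  tmp <- withr::local_tempfile(fileext = ".csv")

  gap2 <- base
  gap2$ax[50:51] <- NA
  write.csv(gap2, tmp, row.names = FALSE)
  expect_message(rec <- read_imu_csv(tmp), "interpolated 2")
  ora <- approx(t[-(50:51)], sin(t)[-(50:51)], xout = t[50:51])$y
  expect_equal(rec$accel[50:51, 1], ora, tolerance = 1e-12)

  gap5 <- base
  gap5$ax[40:44] <- NA
  write.csv(gap5, tmp, row.names = FALSE)
  expect_error(read_imu_csv(tmp), "gap longer than")

  many <- base
  many$ax[seq(5, 95, by = 10)] <- NA
  many$ay[seq(6, 96, by = 10)] <- NA
  write.csv(many, tmp, row.names = FALSE)
  expect_error(read_imu_csv(tmp), "more than 5%")
})

test_that("code event parsing validates enums and handles empty logs", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(subject_id = "S1", phase = "AcuteThreat",
                   valence = "fear", channel = "nonverbal",
                   intensity = "high", duration = 2.0)
  write.csv(df, tmp, row.names = FALSE)
  ev <- read_code_events(tmp)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$duration, 2.0)
  expect_equal(ev$intensity, "high")

  write.csv(df[0, ], tmp, row.names = FALSE)
  expect_equal(nrow(read_code_events(tmp)), 0)

  df$intensity <- "extreme"
  write.csv(df, tmp, row.names = FALSE)
  expect_error(read_code_events(tmp), "row 1.*intensity")
})

test_that("subject metadata validation enforces T-score and dx domains", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  meta <- data.frame(subject_id = "S1", age = 5, gender = "female",
                     cbcl_internalizing = 55, cbcl_externalizing = 60,
                     internalizing_dx = "current", externalizing_dx = FALSE)
  write.csv(meta, tmp, row.names = FALSE)
  expect_silent(read_subject_meta(tmp))

  bad <- meta; bad$cbcl_internalizing <- 150
  write.csv(bad, tmp, row.names = FALSE)
  expect_error(read_subject_meta(tmp), "\\[20, 110\\]")

  bad <- meta; bad$internalizing_dx <- "maybe"
  write.csv(bad, tmp, row.names = FALSE)
  expect_error(read_subject_meta(tmp), "none/past/current")
})

test_that("feature table round-trips losslessly in long format", {
  feats <- make_plain_cohort(n = 3, seed = 5)
  feats$age <- c(4.5, 5, 6.2)
  feats$gender <- c("female", "male", "female")
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(feats, tmp)
  long <- read.csv(tmp)
  # 18 motion rows per subject in long form
  expect_equal(nrow(long), 3 * 18)
  back <- read_feature_table(tmp)
  back <- back[order(back$subject_id), c(names(feats))]
  rownames(back) <- NULL
  expect_equal(back, feats, tolerance = 1e-9)

  expect_error(write_feature_table(feats, tmp), "refusing to overwrite")
  expect_error(write_feature_table(feats[0, ], tempfile()), "empty")
})
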