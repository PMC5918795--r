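test_that("phase windows have exact sample counts and bounds", {
  t <- seq(0, 60, by = 0.01)
  w <- segment_phases(t, 30, sample_rate = 100)
  expect_equal(w$windows$n_samples, c(2000L, 600L, 2000L))
  expect_equal(w$windows$start_s, c(7, 27, 33))
  expect_equal(w$windows$end_s, c(27, 33, 53))
  # contiguous, non-overlapping index coverage
  expect_equal(w$windows$i_start[-1], w$windows$i_end[-3] + 1L)

  expect_error(segment_phases(t, 10), "PotentialThreat")
  expect_error(segment_phases(t, 55), "ResponseModulation")
})

test_that("boundary samples go to the later window (half-open rule)", {
  t <- seq(0, 60, by = 0.02)  # 50 Hz, startle exactly on a sample
  w <- segment_phases(t, 30, sample_rate = 50)
  expect_equal(w$windows$n_samples, c(1000L, 300L, 1000L))
  # the sample at exactly t_startle - 3 s opens the Startle window
  i_s_start <- w$windows$i_start[2]
  expect_equal(t[i_s_start], 27)
  expect_equal(t[w$windows$i_end[1]], 27 - 0.02)
  # sub-sample startle times floor to the same anchor
  w2 <- segment_phases(t, 30.013, sample_rate = 50)
  expect_equal(w2$windows[, c("i_start", "i_end")],
               w$windows[, c("i_start", "i_end")])
})

make_decomposed <- function(t, a_h = 0, a_v = 0, w_h = 0, w_v = 0) {
  n <- length(t)
  rep_n <- function(x) if (length(x) == 1) rep(x, n) else x
  structure(list(t = t, a_v = rep_n(a_v), a_h = rep_n(a_h),
                 w_v = rep_n(w_v), w_h = rep_n(w_h)),
            class = "decomposed_motion")
}

make_orient <- function(t, alpha = 0, gamma = 0) {
  n <- length(t)
  rep_n <- function(x) if (length(x) == 1) rep(x, n) else x
  structure(list(t = t, alpha = rep_n(alpha), gamma = rep_n(gamma),
                 g_hat = matrix(rep(c(0, 0, -1), each = n), n, 3)),
            class = "orientation_trace")
}

test_that("rms and rom match closed forms on constant and sinusoidal input", {
  t <- seq(0, 60, by = 0.01)
  w <- segment_phases(t, 30)
  # constants: rms of a constant is the constant; zero stays zero
  dm <- make_decomposed(t, a_h = 2, a_v = 0)
  orient <- make_orient(t, alpha = 5, gamma = 7)
  f <- compute_phase_features(dm, orient, w, "c")
  expect_equal(f$ah_rms_pt, 2)
  expect_equal(f$av_rms_pt, 0)
  expect_equal(f$alpha_rom_s, 0)
  expect_equal(f$gamma_rom_rm, 0)

  # sinusoid: rms = A/sqrt(2); integral rom = 2A/(2 pi f)
  wv <- 10 * sin(2 * pi * 0.5 * t)
  gamma <- -(10 / pi) * cos(2 * pi * 0.5 * t)
  dm2 <- make_decomposed(t, w_v = wv)
  o2 <- make_orient(t, gamma = gamma)
  f2 <- compute_phase_features(dm2, o2, w, "sin")
  expect_equal(f2$wv_rms_pt, 10 / sqrt(2), tolerance = 0.05 / (10 / sqrt(2)))
  expect_equal(f2$gamma_rom_pt, 2 * 10 / (2 * pi * 0.5),
               tolerance = 0.1 / 6.366)
})

test_that("rms scaling, rom translation and window locality hold", {
  set.seed(17)
  t <- seq(0, 60, by = 0.01)
  w <- segment_phases(t, 30)
  x <- abs(rnorm(length(t)))
  gam <- cumsum(rnorm(length(t))) / 10
  dm <- make_decomposed(t, a_h = x)
  orient <- make_orient(t, gamma = gam)
  f <- compute_phase_features(dm, orient, w, "p")
  # homogeneity of rms
  dm_c <- make_decomposed(t, a_h = 3.7 * x)
  f_c <- compute_phase_features(dm_c, orient, w, "p")
  for (ph in c("pt", "s", "rm"))
    expect_equal(f_c[[paste0("ah_rms_", ph)]],
                 3.7 * f[[paste0("ah_rms_", ph)]], tolerance = 1e-12)
  # translation invariance of rom
  o_c <- make_orient(t, gamma = gam + 123.4)
  f_t <- compute_phase_features(dm, o_c, w, "p")
  expect_equal(f_t$gamma_rom_pt, f$gamma_rom_pt, tolerance = 1e-12)
  # perturbing samples outside a window never changes that window
  x2 <- x
  outside <- setdiff(seq_along(t), w$windows$i_start[1]:w$windows$i_end[1])
  x2[outside] <- x2[outside] + 100
  f_o <- compute_phase_features(make_decomposed(t, a_h = x2), orient, w, "p")
  expect_identical(f_o$ah_rms_pt, f$ah_rms_pt)
  # brute-force recomputation oracle
  idx <- w$windows$i_start[2]:w$windows$i_end[2]
  expect_equal(f$ah_rms_s, sqrt(sum(x[idx]^2) / length(idx)),
               tolerance = 1e-12)
  expect_equal(f$gamma_rom_s, max(gam[idx]) - min(gam[idx]),
               tolerance = 1e-12)
})

test_that("cohort extraction excludes uncovered subjects with a reason", {
  set.seed(3)
  cfg <- sim_config(n_subjects = 1, seed = 3)
  recs <- list()
  for (i in 1:3) {
    sim <- simulate_subject_motion(cfg, sprintf("S%d", i))
    recs[[i]] <- sim$recording
  }
  ann <- data.frame(subject_id = c("S1", "S2", "S3"),
                    t_startle = c(26, 26.5, 5))  # S3 too early
  res <- compute_cohort_features(recs, ann)
  expect_equal(nrow(res$features), 2)
  expect_equal(res$exclusions$subject_id, "S3")
  expect_match(res$exclusions$reason, "PotentialThreat")
  expect_false(anyNA(res$features[, -1]))

  recs_dup <- c(recs, recs[1])
  expect_error(compute_cohort_features(recs_dup, ann), "duplicate")
})
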