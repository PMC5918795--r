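test_that("paired phase t equals the hand formula on a 5-pair dataset", {
  tab <- make_plain_cohort(n = 5, seed = 41)
  pt <- c(1.2, 3.4, 2.2, 5.0, 4.1)
  s <- c(2.0, 3.1, 4.4, 5.5, 6.0)
  tab$ah_rms_pt <- pt
  tab$ah_rms_s <- s
  fc <- structure(list(data = tab, descriptive = tab,
                       provenance = NULL), class = "fear_cohort")
  res <- paired_phase_tests(fc)
  row <- res[res$variable == "ah_rms" & res$comparison == "PT-S", ]
  d <- pt - s
  t_oracle <- mean(d) / (sd(d) / sqrt(5))
  expect_equal(row$t, t_oracle, tolerance = 1e-12)
  expect_equal(row$n, 5)
  expect_equal(row$mean_diff, mean(d), tolerance = 1e-12)
})

test_that("paired t sign convention: larger second phase drives t negative", {
  set.seed(43)
  tab <- make_plain_cohort(n = 30, seed = 43)
  tab$gamma_rom_s <- tab$gamma_rom_pt + 1 + rnorm(30, sd = 0.01)
  res <- paired_phase_tests(tab)
  expect_lt(res$t[res$variable == "gamma_rom" & res$comparison == "PT-S"],
            -10)
  # zero-variance differences are an error, not a silent NA
  tab$wv_rms_s <- tab$wv_rms_pt
  expect_error(paired_phase_tests(tab), "zero-variance")
})

test_that("null phase differences rarely reach significance", {
  set.seed(45)
  hits <- 0
  for (i in 1:30) {
    x <- rnorm(40)
    y <- x + rnorm(40)
    hits <- hits + (t.test(x, y, paired = TRUE)$p.value < 0.05)
  }
  expect_lte(hits / 30, 0.2)
})

test_that("modality correlations match the covariance-formula oracle", {
  tab <- make_plain_cohort(n = 6, seed = 47)
  x <- c(3.1, 4.5, 2.2, 6.6, 5.0, 3.9)
  tab$ah_rms_s <- x
  y <- c(8, 12, 5, 20, 14, 9.5)
  tab$fear_at <- y
  fc <- structure(list(data = tab, descriptive = tab, provenance = NULL),
                  class = "fear_cohort")
  res <- correlate_modalities(fc)
  row <- res[res$variable == "ah_rms" & res$phase == "S", ]
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(row$r, r_oracle, tolerance = 1e-12)
  expect_equal(row$code_phase, "AcuteThreat")

  # exact linear relation gives r = 1
  tab$ah_rms_pt <- 1:6
  tab$fear_pt <- 2 * (1:6) + 1
  fc2 <- structure(list(data = tab, descriptive = tab, provenance = NULL),
                   class = "fear_cohort")
  res2 <- correlate_modalities(fc2)
  expect_equal(res2$r[res2$variable == "ah_rms" & res2$phase == "PT"], 1,
               tolerance = 1e-12)
})

test_that("independent null pairs keep correlations near zero", {
  set.seed(49)
  rs <- replicate(40, cor(rnorm(56), rnorm(56)))
  expect_lt(abs(mean(rs)), 0.06)
  expect_lte(mean(abs(rs) > 0.3), 0.05)
})

test_that("symptom correlations and Spearman screen match rank oracles", {
  tab <- make_plain_cohort(n = 10, seed = 51)
  tab$cbcl_internalizing <- c(40, 55, 61, 48, 52, 66, 45, 58, 50, 63)
  tab$cbcl_externalizing <- c(44, 60, 50, 41, 57, 70, 46, 55, 49, 65)
  tab$age <- c(3.5, 4, 4.5, 5, 5.5, 6, 6.5, 7, 4.2, 5.8)
  tab$gender <- rep(c("female", "male"), 5)
  res <- correlate_symptoms(
    structure(list(data = tab, descriptive = tab, provenance = NULL),
              class = "fear_cohort"))
  row <- res$symptoms[res$symptoms$variable == "ah_rms" &
                        res$symptoms$phase == "PT" &
                        res$symptoms$scale == "externalizing", ]
  expect_equal(row$r, cor(tab$ah_rms_pt, tab$cbcl_externalizing),
               tolerance = 1e-12)
  # Spearman equals Pearson on (tied) ranks
  crow <- res$covariates[res$covariates$variable == "fear" &
                           res$covariates$phase == "PT" &
                           res$covariates$covariate == "gender", ]
  g <- as.numeric(factor(tab$gender)) - 1
  expect_equal(crow$rho, cor(rank(tab$fear_pt), rank(g)), tolerance = 1e-12)
  # a measure distributed identically across genders has rho 0
  tab2 <- tab
  tab2$gender <- rep(c("female", "male"), each = 5)
  tab2$fear_pt <- rep(c(5, 7, 9, 6, 8), 2)
  res2 <- correlate_symptoms(tab2)
  crow2 <- res2$covariates[res2$covariates$variable == "fear" &
                             res2$covariates$phase == "PT" &
                             res2$covariates$covariate == "gender", ]
  expect_equal(crow2$rho, 0, tolerance = 1e-12)
})

test_that("diagnosis comparison matches pooled-variance hand formulas", {
  tab <- make_plain_cohort(n = 8, seed = 53)
  x0 <- c(1.0, 1.4, 0.8, 1.2)   # no diagnosis
  x1 <- c(1.9, 2.3, 1.6, 2.1)   # diagnosed
  tab$ah_rms_pt <- c(x0, x1)
  tab$internalizing_dx <- c(rep("none", 4), "past", rep("current", 3))
  tab$externalizing_dx <- FALSE
  res <- compare_diagnosis_groups(tab)
  row <- res[res$variable == "ah_rms" & res$phase == "PT", ]
  sp <- sqrt((3 * var(x0) + 3 * var(x1)) / 6)
  t_oracle <- (mean(x0) - mean(x1)) / (sp * sqrt(1 / 4 + 1 / 4))
  d_oracle <- (mean(x1) - mean(x0)) / sp
  expect_equal(row$t, t_oracle, tolerance = 1e-12)
  expect_equal(row$cohen_d, d_oracle, tolerance = 1e-12)
  expect_equal(c(row$n_none, row$n_dx), c(4L, 4L))
  expect_lt(row$t, 0)  # diagnosed group higher -> negative t
  expect_equal(row$significance, "sig")
})

test_that("externalizing-exclusion sensitivity rerun drops flagged subjects", {
  tab <- make_plain_cohort(n = 12, seed = 55)
  tab$internalizing_dx <- rep(c("none", "current"), 6)
  tab$externalizing_dx <- c(TRUE, TRUE, rep(FALSE, 10))
  res_all <- compare_diagnosis_groups(tab)
  res_ex <- compare_diagnosis_groups(tab, exclude_externalizing = TRUE)
  expect_equal(res_all$n_none[1] + res_all$n_dx[1], 12L)
  expect_equal(res_ex$n_none[1] + res_ex$n_dx[1], 10L)
})

test_that("descriptives report the winsorized scale with hand-checked values", {
  tab <- make_plain_cohort(n = 4, seed = 57)
  tab$wh_rms_pt <- c(1, 2, 3, 4)
  fc <- structure(list(data = tab, descriptive = tab,
                       provenance = data.frame(variable = "wh_rms_pt",
                                               winsorized = FALSE,
                                               log_transformed = FALSE)),
                  class = "fear_cohort")
  res <- describe_variables(fc)
  row <- res[res$variable == "wh_rms" & res$phase == "PT", ]
  expect_equal(row$mean, 2.5)
  expect_equal(row$sd, sd(c(1, 2, 3, 4)), tolerance = 1e-12)
  expect_equal(sqrt(5 / 3), row$sd, tolerance = 1e-12)
  expect_equal(c(row$min, row$max), c(1, 4))

  # constant variable: sd 0, degenerate but reportable; winsorized
  # variables report the post-clamp range
  set.seed(58)
  tab3 <- make_plain_cohort(n = 40, seed = 59)
  tab3$av_rms_s <- 7
  tab3$ah_rms_rm <- c(rnorm(38, 10), 80, 90)
  fc3 <- clean_cohort(tab3)
  res3 <- describe_variables(fc3)
  row2 <- res3[res3$variable == "av_rms" & res3$phase == "S", ]
  expect_equal(c(row2$mean, row2$sd, row2$min, row2$max), c(7, 0, 7, 7))
  row3 <- res3[res3$variable == "ah_rms" & res3$phase == "RM", ]
  expect_true(row3$winsorized)
  expect_equal(row3$max, quantile(tab3$ah_rms_rm, 0.95, type = 7,
                                  names = FALSE))
})

test_that("regression wrapper reproduces the underlying glm", {
  tab <- make_plain_cohort(n = 20, seed = 61)
  tab$internalizing_dx <- rep(c("none", "current"), 10)
  fit <- fit_outcome(tab, internalizing_dx_flag ~ ah_rms_pt,
                     family = binomial())
  expect_s3_class(fit, "glm")
  expect_equal(length(coef(fit)), 2)
})
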