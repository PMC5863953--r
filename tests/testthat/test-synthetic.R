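make_small_dataset <- function(seed = 3) {
  # tiny physical population: 2 dyads, short blocks and trials
  generate_dyad_dataset(
    n_dyads = 2, strategy = "goal_integration", seed = seed,
    noise_model = haptic_noise_model(c(hard = 0, medium = 0, soft = 0)),
    duration = 10, n_per_block = 4
  )
}

test_that("generated dyad datasets have the record structure", {
  gd <- make_small_dataset()
  rec <- gd$records
  expect_s3_class(rec, "dyad_records")
  expect_equal(ncol(rec), 19)
  expect_true(all(rec$solo_error_1 > 0))
  expect_true(all(rec$order %in% c(0, 1)))
  # order constant within dyad
  expect_true(all(tapply(rec$order, rec$dyad, function(x) {
    length(unique(x))
  }) == 1))
  # stiffness stored in Nm/deg, matching the three levels
  expect_true(all(round(rec$stiffness_nm_deg, 2) %in%
                    round(nm_per_rad_to_nm_per_deg(stiffness_levels()), 2)))
  # determinism: same seed, byte-identical table
  gd2 <- make_small_dataset()
  expect_identical(gd$records, gd2$records)
})

test_that("equal-skill dyads have relative error centred at zero", {
  nm <- haptic_noise_model(c(hard = 0, medium = 0, soft = 0))
  gd <- generate_dyad_dataset(n_dyads = 3, strategy = "goal_integration",
                              seed = 5, skill_range = c(3, 3),
                              noise_model = nm, duration = 10,
                              n_per_block = 4)
  expect_lt(abs(mean(gd$paired$delta_p)), 0.08)
})

test_that("record files round-trip losslessly through the text dialect", {
  gd <- make_small_dataset()
  f <- tempfile(fileext = ".txt")
  write_s1(gd$records, f)
  back <- read_s1(f)
  expect_equal(as.data.frame(back), as.data.frame(gd$records),
               tolerance = 1e-12)
  unlink(f)
})

test_that("record parser rejects malformed files", {
  gd <- make_small_dataset()
  f <- tempfile(fileext = ".txt")
  # 18 columns
  utils::write.table(as.data.frame(gd$records)[, -5], f, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  expect_error(read_s1(f), "19 columns")
  # 20 columns
  d20 <- cbind(as.data.frame(gd$records), extra = 1)
  utils::write.table(d20, f, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  expect_error(read_s1(f), "19 columns")
  # negative error cell
  bad <- as.data.frame(gd$records)
  bad$solo_error_1[2] <- -1
  utils::write.table(bad, f, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  expect_error(read_s1(f), "errors")
  # stiffness that matches no level
  bad2 <- as.data.frame(gd$records)
  bad2$stiffness_nm_deg <- 7
  utils::write.table(bad2, f, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  expect_error(read_s1(f), "stiffness")
  unlink(f)
})

test_that("records expand to paired outcomes with consistent ratios", {
  gd <- make_small_dataset()
  pp <- records_to_paired(gd$records)
  expect_s3_class(pp, "paired_outcomes")
  expect_equal(nrow(pp), 2 * nrow(gd$records))
  j <- 3
  r <- gd$records[j, ]
  expect_equal(pp$delta_c[2 * j - 1],
               1 - r$conn_error_1 / r$solo_error_1)
  expect_equal(pp$delta_p[2 * j],
               1 - r$solo_error_1 / r$solo_error_2)
  expect_true(all(abs(pp$stiffness -
                        nm_per_deg_to_nm_per_rad(rep(gd$records$stiffness_nm_deg,
                                                     each = 2))) < 1e-9))
})

test_that("haptic tracking tables round-trip and validate", {
  # synthetic 8-subject table in the 30-row dialect
  set.seed(1)
  rec <- data.frame(
    subject = rep(1:8, each = 15),
    trial = rep(1:15, 8),
    stiffness = rep(rep(stiffness_levels(), each = 5), 8),
    error_deg = stats::runif(120, 0.5, 5)
  )
  f <- tempfile(fileext = ".txt")
  write_s2(rec, f)
  back <- read_s2(f)
  expect_equal(ncol(matrix(0, 1, 8)), 8)
  expect_equal(length(unique(back$subject)), 8)
  expect_equal(back$error_deg, rec$error_deg, tolerance = 1e-9)
  expect_equal(back$stiffness, rec$stiffness, tolerance = 1e-9)

  # corrupt a stiffness block so rows are not constant in fives
  m <- as.matrix(utils::read.table(f))
  m[16, 1] <- m[16, 1] * 2
  utils::write.table(m, f, sep = "\t", row.names = FALSE, col.names = FALSE)
  expect_error(read_s2(f), "blocks of 5")
  unlink(f)
})

test_that("regression-level generator plants detectable structure", {
  # a planted stiffness effect is detected with high power
  detections <- vapply(1:12, function(s) {
    pp <- simulate_paired_outcomes(seed = s)
    lrt <- likelihood_ratio_test(fit_improvement_lme(pp),
                                 fit_improvement_lme(pp,
                                                     include_stiffness = FALSE))
    lrt$p_value < 0.05
  }, logical(1))
  expect_gte(mean(detections), 0.8)
})
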