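test_that("the seven canonical genotypes are constructible and distinct", {
  g <- canonical_genotypes()
  expect_equal(nrow(g), 7)
  expect_equal(anyDuplicated(g$id), 0)
  expect_setequal(unique(g$group), c("HEB", "Bowman"))
  # Bowman lines all share the recessive ppd-H1 background
  expect_true(all(g$ppdh1[g$group == "Bowman"] == "Hv"))
  expect_error(genotype_spec("bad", "Bowman", "Hv", "Hsp"),
               "recessive ppd-H1")
})

test_that("response_params enforces its invariants", {
  p <- response_params(600, 50, 20, 10)
  expect_s3_class(p, "response_params")
  expect_error(response_params(-5, 50, 20, 10))
  expect_error(response_params(600, -1, 20, 10))
  expect_error(response_params(600, 50, 20, 0))
  expect_error(response_params(600, 50, 25, 10), "outside bounds")
  # flat genotypes drop the threshold
  expect_true(is.na(response_params(600, 0, NA, 10)$T))
})

test_that("phenotype CSV round-trips losslessly and validates", {
  ph <- tiny_phenotypes()
  path <- withr::local_tempfile(fileext = ".csv")
  write_phenotypes(ph, path)
  expect_identical(readLines(path, n = 1), "#schema=photothermal-v1")
  back <- read_phenotypes(path)
  expect_equal(back, ph, tolerance = 1e-12)

  bad <- ph; bad$photoperiod_h[2] <- 25
  expect_error(write_phenotypes(bad, path), "outside \\[0, 24\\]")
  bad2 <- ph; bad2$thermal_time_cd[1] <- NA
  expect_error(validate_phenotypes(bad2), "thermal_time_cd")
  # days_to_heading may be absent when thermal time is supplied
  ok <- ph; ok$days_to_heading <- NA_real_
  expect_silent(validate_phenotypes(ok))
})

test_that("schema errors name the missing column", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("#schema=photothermal-v1", "genotype,photoperiod_h", "g,16"),
             path)
  expect_error(read_phenotypes(path), "thermal_time_cd")
})

test_that("temperature and Ct tables round-trip", {
  log <- generate_temperature_log(days = 2, mean_c = 20, sd_c = 0.5,
                                  seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_temperature_log(log, path)
  back <- read_temperature_log(path)
  expect_equal(as.numeric(back$timestamp), as.numeric(log$timestamp))
  expect_equal(back$temp_c, log$temp_c, tolerance = 1e-6)

  eff <- data.frame(gene = c("HvTubA", "FT1"), genotype = "g",
                    photoperiod_h = 16, zt = 5, mean_ct = c(22, 30),
                    p_undetected = c(0, 0.5))
  ct <- generate_ct_table(eff, seed = 4)
  ctp <- withr::local_tempfile(fileext = ".csv")
  write_ct_table(ct, ctp)
  back <- read_ct_table(ctp)
  expect_equal(back$undetected, ct$undetected)
  expect_equal(back$ct, ct$ct, tolerance = 1e-6)
})

test_that("thermal time accumulates daily means above base", {
  log <- generate_temperature_log(days = 40, mean_c = 20, sd_c = 0)
  t0 <- log$timestamp[1]
  expect_equal(accumulate_thermal_time(log, t0, t0 + 40 * 86400), 800)
  expect_equal(accumulate_thermal_time(log, t0, t0 + 40 * 86400,
                                       base_temp = 20), 0)
  # alternating 18/22 degC days: mean 20 over 10 days
  alt <- generate_temperature_log(days = 10, mean_c = 0, sd_c = 0)
  alt$temp_c <- ifelse(as.integer(format(alt$timestamp, "%d")) %% 2 == 1,
                       18, 22)
  expect_equal(accumulate_thermal_time(alt, alt$timestamp[1],
                                       alt$timestamp[1] + 10 * 86400), 200)
  # constant temperature: both accumulation methods agree exactly
  expect_equal(
    accumulate_thermal_time(log, t0, t0 + 40 * 86400,
                            method = "per_reading"), 800)
})

test_that("thermal time is additive over adjacent windows", {
  log <- generate_temperature_log(days = 30, mean_c = 19, sd_c = 1.5,
                                  seed = 11)
  t0 <- log$timestamp[1]
  for (split_day in c(7, 12, 21)) {
    tt_ab <- accumulate_thermal_time(log, t0, t0 + split_day * 86400)
    tt_bc <- accumulate_thermal_time(log, t0 + split_day * 86400,
                                     t0 + 30 * 86400)
    tt_ac <- accumulate_thermal_time(log, t0, t0 + 30 * 86400)
    expect_equal(tt_ab + tt_bc, tt_ac, tolerance = 1e-9)
  }
})

test_that("thermal time rejects bad windows and warns on gaps", {
  log <- generate_temperature_log(days = 5, mean_c = 20, sd_c = 0)
  t0 <- log$timestamp[1]
  expect_error(accumulate_thermal_time(log, t0 + 86400, t0), "precede")
  expect_error(accumulate_thermal_time(log, t0 - 86400, t0 + 86400),
               "outside the span")
  gappy <- log[-(10:20), ]
  expect_warning(
    accumulate_thermal_time(gappy, t0, t0 + 5 * 86400), "gap")
})

test_that("planting density rounds half-up", {
  expect_equal(planting_density(35, 0.64), 55)
  expect_equal(planting_density(64, 0.64), 100)
  expect_equal(planting_density(0, 0.64), 0)
  expect_error(planting_density(35, 0), "positive")
})
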