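test_that("the default design yields the full factorial record count", {
  ph <- generate_phenotypes(design_spec(seed = 1))
  expect_equal(nrow(ph), 7 * 5 * 5 * 2)
  counts <- table(ph$genotype, ph$photoperiod_h)
  expect_true(all(counts == 10))  # 5 replicates x 2 repetitions
})

test_that("noise-free generation returns the bi-linear means exactly", {
  g <- genotype_spec("solo", "HEB", "Hv", "Hv")
  prm <- list(solo = response_params(600, 50, 20, sigma = 1e-9))
  d <- design_spec(genotypes = g, params = prm, photoperiods_h = 16,
                   replicates = 4, repetitions = 1, seed = 5)
  ph <- generate_phenotypes(d)
  expect_equal(ph$thermal_time_cd, rep(800, 4), tolerance = 1e-6)
})

test_that("generation is reproducible by seed and varies across seeds", {
  a <- generate_phenotypes(design_spec(seed = 42))
  b <- generate_phenotypes(design_spec(seed = 42))
  c <- generate_phenotypes(design_spec(seed = 43))
  expect_identical(a, b)
  expect_false(identical(a$thermal_time_cd, c$thermal_time_cd))
})

test_that("a flat genotype shows no systematic 16h vs 24h difference", {
  g <- genotype_spec("flat", "HEB", "Hv", "Hsp")
  sigma <- 20
  prm <- list(flat = response_params(550, 0, NA, sigma = sigma))
  d <- design_spec(genotypes = g, params = prm, replicates = 200,
                   repetitions = 2, seed = 8)
  ph <- generate_phenotypes(d)
  m16 <- mean(ph$thermal_time_cd[ph$photoperiod_h == 16])
  m24 <- mean(ph$thermal_time_cd[ph$photoperiod_h == 24])
  se <- sigma * sqrt(2 / 400)
  expect_lt(abs(m16 - m24), 3 * se)
})

test_that("large-replicate genotype means converge to the generating curve", {
  d <- design_spec(replicates = 500, repetitions = 1, seed = 21)
  ph <- generate_phenotypes(d)
  for (gid in d$genotypes$id) {
    p <- d$params[[gid]]
    for (pp in d$photoperiods_h) {
      y <- ph$thermal_time_cd[ph$genotype == gid & ph$photoperiod_h == pp]
      mu <- if (p$S == 0) p$I else p$I + p$S * max(0, p$T - pp)
      expect_lt(abs(mean(y) - mu), 3 * p$sigma / sqrt(500))
    }
  }
})

test_that("the repetition shift moves only repetition 2", {
  g <- genotype_spec("solo", "HEB", "Hv", "Hv")
  prm <- list(solo = response_params(600, 0, NA, sigma = 1e-9))
  d <- design_spec(genotypes = g, params = prm, photoperiods_h = 20,
                   replicates = 3, repetitions = 2, seed = 2,
                   repetition_shift = 40)
  ph <- generate_phenotypes(d)
  expect_equal(unique(round(ph$thermal_time_cd[ph$repetition == 1])), 600)
  expect_equal(unique(round(ph$thermal_time_cd[ph$repetition == 2])), 640)
})

test_that("temperature log generation matches its contract", {
  log <- generate_temperature_log(days = 10, sd_c = 0)
  expect_equal(nrow(log), 480)
  expect_true(all(log$temp_c == 20))
  # noisy log: daily means stay within a 4-sigma band of the setpoint
  noisy <- generate_temperature_log(days = 100, sd_c = 0.5, seed = 31)
  daily <- tapply(noisy$temp_c, format(noisy$timestamp, "%Y-%m-%d"), mean)
  expect_true(all(abs(daily - 20) < 4 * 0.5 / sqrt(48)))
})

test_that("Ct table generation respects counts, flags and zero variance", {
  eff <- expand.grid(gene = c("PPD-H1", "FT1"),
                     genotype = paste0("g", 1:4),
                     photoperiod_h = c(16, 22), zt = c(5, 11, 17, 23),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  eff$mean_ct <- 25
  ct <- generate_ct_table(eff, bio_reps = 2, tech_reps = 2, seed = 6)
  expect_equal(nrow(ct), 2 * 4 * 2 * 4 * 2 * 2)

  eff1 <- data.frame(gene = "FT1", genotype = "g", photoperiod_h = 16,
                     zt = 5, mean_ct = 30, p_undetected = 1)
  expect_true(all(generate_ct_table(eff1, seed = 1)$undetected))

  eff0 <- data.frame(gene = "FT1", genotype = "g", photoperiod_h = 16,
                     zt = 5, mean_ct = 30)
  exact <- generate_ct_table(eff0, sigma_bio = 0, sigma_tech = 0, seed = 1)
  expect_true(all(exact$ct == 30))

  effbad <- data.frame(gene = "FT1", genotype = "g", photoperiod_h = 16,
                       zt = 5, mean_ct = 30, p_undetected = 1.5)
  expect_error(generate_ct_table(effbad), "\\[0, 1\\]")
})

test_that("a non-positive sigma is rejected at design time", {
  g <- genotype_spec("solo", "HEB", "Hv", "Hv")
  prm <- list(solo = list(I = 600, S = 0, T = NA, sigma = 0))
  expect_error(design_spec(genotypes = g, params = prm), "sigma")
})
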