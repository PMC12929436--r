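test_that("predict_mean reproduces hinge arithmetic", {
  p <- response_params(600, 50, 20, 10)
  expect_equal(predict_mean(p, 22), 600)
  expect_equal(predict_mean(p, 16), 800)
  expect_equal(predict_mean(response_params(600, 0, NA, 10), 16), 600)
  expect_error(predict_mean(p, 25), "\\[0, 24\\]")
})

test_that("the mean curve is non-increasing and constant past the threshold", {
  set.seed(14)
  grid <- seq(0, 24, by = 0.25)
  for (i in 1:25) {
    p <- response_params(I = runif(1, 300, 900), S = runif(1, 0, 80),
                         T = runif(1, 12, 24), sigma = 1)
    mu <- predict_mean(p, grid)
    expect_true(all(diff(mu) <= 1e-12))
    expect_true(all(abs(mu[grid >= (if (is.na(p$T)) 0 else p$T)] - p$I)
                    < 1e-12))
  }
})

test_that("noise-free data recovers the generating parameters", {
  rec <- make_records(620, 45, 19.5, sigma = 0, n_per_p = 20)
  f <- fit_photoperiod_model(rec, "full")
  expect_equal(f$params$g$I, 620, tolerance = 1e-3)
  expect_equal(f$params$g$S, 45, tolerance = 1e-3)
  expect_equal(f$params$g$T, 19.5, tolerance = 1e-3)
  expect_true(f$converged)
  # the fitted curve honours the estimates
  expect_equal(f$fitted_curve("g", 16), 620 + 45 * 3.5, tolerance = 1e-2)
})

test_that("fit matches the independent grid-search + lm oracle", {
  set.seed(20)
  for (r in 1:20) {
    I <- runif(1, 450, 700); S <- runif(1, 20, 60)
    T <- runif(1, 18.5, 21.5); sg <- runif(1, 5, 20)
    rec <- make_records(I, S, T, sg, n_per_p = 8)
    f <- fit_photoperiod_model(rec, "full")
    o <- oracle_hinge_fit(rec$photoperiod_h, rec$thermal_time_cd)
    expect_lt(abs(f$params$g$I - o$I), 0.5)
    expect_lt(abs(f$params$g$S - o$S), 0.05)
  }
})

test_that("estimates are invariant to record order", {
  rec <- make_records(600, 50, 20, 10, n_per_p = 10, seed = 33)
  f1 <- fit_photoperiod_model(rec, "full")
  set.seed(1); f2 <- fit_photoperiod_model(rec[sample(nrow(rec)), ], "full")
  for (p in c("I", "S", "T", "sigma")) {
    expect_equal(f1$params$g[[p]], f2$params$g[[p]], tolerance = 1e-9)
  }
})

test_that("flat data yields a near-zero slope and a non-identifiable threshold", {
  rec <- make_records(550, 0, NA, 15, n_per_p = 50, seed = 9)
  f <- fit_photoperiod_model(rec, "full")
  e <- f$estimates
  s <- e[e$parameter == "S", ]
  expect_lt(s$lower, 2)   # interval reaches into the near-zero band
  if (f$params$g$S == 0) {
    expect_true(is.na(f$params$g$T))
    expect_match(paste(f$warnings, collapse = " "), "not identifiable")
  }
  cls <- classify_response(f, tested_range = c(16, 24))
  expect_true(cls$classification %in% c("flat_saturated", "indeterminate"))
})

test_that("single-photoperiod genotypes raise an identifiability error", {
  rec <- make_records(600, 50, 20, 5, n_per_p = 10, photoperiods = 16)
  expect_error(fit_photoperiod_model(rec, "full"), "single photoperiod")
})

test_that("variant comparison ranks by criterion with deterministic ties", {
  rec_flat <- make_records(550, 0, NA, 15, n_per_p = 20, seed = 101)
  cmp <- compare_variants(rec_flat, list("full", "flat"))
  expect_equal(cmp$best, "flat")
  rec_resp <- make_records(600, 50, 20, 15, n_per_p = 20, seed = 102)
  cmp2 <- compare_variants(rec_resp, list("full", "flat"))
  expect_equal(cmp2$best, "full")
  # a single variant passes through with its fit
  cmp3 <- compare_variants(rec_resp, list("full"))
  expect_equal(names(cmp3$fits), "full")
  expect_equal(nrow(cmp3$table), 1)
})

test_that("a shared-threshold variant pools the breakpoint across genotypes", {
  set.seed(55)
  rec <- rbind(make_records(650, 45, 20, 10, n_per_p = 20, genotype = "a"),
               make_records(550, 30, 20, 10, n_per_p = 20, genotype = "b"))
  f <- fit_photoperiod_model(rec, "shared_T")
  expect_equal(f$params$a$T, f$params$b$T)
  expect_equal(f$params$a$T, 20, tolerance = 0.3)
  expect_equal(f$k, 2 * 3 + 1)
})

test_that("classification follows the slope-interval rule", {
  rec <- make_records(600, 50, 20, 10, n_per_p = 50, seed = 77)
  f <- fit_photoperiod_model(rec, "full")
  cls <- classify_response(f, tested_range = c(16, 24))
  expect_equal(cls$classification, "responsive")

  rec_flat <- make_records(550, 0, NA, 10, n_per_p = 50, seed = 78)
  f2 <- fit_photoperiod_model(rec_flat, "full")
  cls2 <- classify_response(f2, tested_range = c(16, 24))
  expect_equal(cls2$classification, "flat_saturated")
  expect_match(cls2$note, "cannot distinguish")

  # straddling interval with a wide threshold interval -> indeterminate
  f3 <- f
  f3$estimates[f3$estimates$parameter == "S", c("estimate", "lower", "upper")] <-
    list(3, -1, 7)
  f3$params$g$S <- 3
  cls3 <- classify_response(f3, tested_range = c(16, 24))
  expect_equal(cls3$classification, "indeterminate")
})

test_that("classification refuses an unconverged fit", {
  rec <- make_records(600, 50, 20, 10, n_per_p = 10, seed = 1)
  f <- fit_photoperiod_model(rec, "full")
  f$converged <- FALSE
  expect_error(classify_response(f), "unconverged")
})

test_that("recommendations map classes to photoperiods with provenance", {
  cls <- data.frame(
    genotype = c("resp", "flat", "indet"),
    classification = c("responsive", "flat_saturated", "indeterminate"),
    S = c(45, 0, 3), S_lower = c(40, -1, -1), S_upper = c(50, 1, 7),
    T = c(20, NA, NA), note = "", stringsAsFactors = FALSE)
  rec <- recommend_photoperiod(cls)
  expect_equal(rec$recommended_h, c(20, 16, 22))
  expect_true(all(nzchar(rec$recommendation_note)))
  # a threshold between tested photoperiods snaps to the nearest tested
  # one, with ties resolved upward
  cls$T[1] <- 19.3
  expect_equal(recommend_photoperiod(cls)$recommended_h[1], 20)
  cls$T[1] <- 20.4
  expect_equal(recommend_photoperiod(cls)$recommended_h[1], 20)
  cls$T[1] <- 19
  expect_equal(recommend_photoperiod(cls)$recommended_h[1], 20)
})
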