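make_ct <- function(gene, ct, bio_rep = 1L, tech_rep = seq_along(ct),
                    genotype = "g", photoperiod_h = 16, zt = 5) {
  data.frame(gene = gene, genotype = genotype,
             photoperiod_h = photoperiod_h, zt = zt,
             bio_rep = bio_rep, tech_rep = tech_rep,
             ct = ct, undetected = is.na(ct), stringsAsFactors = FALSE)
}

test_that("technical replicates collapse to the detected mean", {
  out <- collapse_tech_reps(make_ct("FT1", c(24.0, 24.4)))
  expect_equal(out$ct, 24.2)
  expect_false(out$partial_detection)

  part <- collapse_tech_reps(make_ct("FT1", c(25.0, NA)))
  expect_equal(part$ct, 25.0)
  expect_true(part$partial_detection)
  expect_false(part$undetected)

  none <- collapse_tech_reps(make_ct("FT1", c(NA, NA)))
  expect_true(none$undetected)
  expect_true(is.na(none$ct))
})

test_that("relative expression follows 2^-deltaCt", {
  ct <- rbind(make_ct("HvTubA", c(22, 22)),
              make_ct("FT1", c(22, 22)))
  expect_equal(relative_expression(ct)$rel_expr, 1)
  ct2 <- rbind(make_ct("HvTubA", c(22, 22)), make_ct("FT1", c(23, 23)))
  expect_equal(relative_expression(ct2)$rel_expr, 0.5)
  ct3 <- rbind(make_ct("HvTubA", c(22, 22)), make_ct("FT1", c(20, 20)))
  expect_equal(relative_expression(ct3)$rel_expr, 4)
})

test_that("relative expression is invariant to a plate-wide Ct shift", {
  set.seed(91)
  eff <- expand.grid(gene = c("HvTubA", "PPD-H1"), genotype = c("a", "b"),
                     photoperiod_h = 16, zt = c(5, 11),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  eff$mean_ct <- runif(nrow(eff), 20, 30)
  ct <- generate_ct_table(eff, seed = 12)
  shifted <- ct
  shifted$ct <- shifted$ct + 1.7
  expect_equal(relative_expression(shifted)$rel_expr,
               relative_expression(ct)$rel_expr, tolerance = 1e-12)
})

test_that("missing or undetected reference wells are flagged, not dropped", {
  ct <- rbind(make_ct("HvTubA", c(NA, NA)), make_ct("FT1", c(24, 24)))
  out <- relative_expression(ct)
  expect_equal(nrow(out), 1)
  expect_false(out$detected)
  expect_equal(out$omit_reason, "reference undetected")
  expect_true(is.na(out$rel_expr))

  only_target <- make_ct("FT1", c(24, 24))
  expect_error(relative_expression(only_target), "reference gene")
})

test_that("expression comparisons test log2 expression and flag untestable cells", {
  # identical groups -> p = 1
  vals <- data.frame(gene = "FT1", genotype = rep(c("a", "b"), each = 2),
                     photoperiod_h = 16, zt = 5, bio_rep = c(1, 2, 1, 2),
                     delta_ct = c(1, 2, 1, 2), rel_expr = 2^-c(1, 2, 1, 2),
                     detected = TRUE, omit_reason = NA_character_)
  out <- compare_expression(vals, list(c("a", "b")))
  expect_equal(out$p_value, 1)
  expect_true(out$testable)

  # a 2-fold difference with modest noise executes and returns a finite p
  set.seed(17)
  eff <- rbind(
    data.frame(gene = "HvTubA", genotype = c("a", "b"), photoperiod_h = 16,
               zt = 5, mean_ct = 22),
    data.frame(gene = "FT1", genotype = c("a", "b"), photoperiod_h = 16,
               zt = 5, mean_ct = c(25, 26)))
  ct <- generate_ct_table(eff, sigma_bio = 0.2, sigma_tech = 0.1, seed = 18)
  smoke <- compare_expression(relative_expression(ct), list(c("a", "b")))
  expect_true(is.finite(smoke$p_value))
  expect_true(smoke$p_value >= 0 && smoke$p_value <= 1)

  # one group fully undetected -> untestable, with the reason recorded
  vals$detected[vals$genotype == "b"] <- FALSE
  out2 <- compare_expression(vals, list(c("a", "b")))
  expect_false(out2$testable)
  expect_match(out2$untestable_reason, "fewer than 2 detected")
})
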