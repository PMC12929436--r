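#' Pairwise photoperiod treatment contrasts
#'
#' Two-sided two-sample Student's t-tests on thermal time to heading
#' between pairs of photoperiod treatments, per genotype. The default
#' pairs probe the two decisions that matter for speed breeding: does
#' extending 16 h to 20 h still accelerate flowering, and does extending
#' 20 h to 22 h (the common speed-breeding photoperiod) add anything.
#'
#' "Student's t-test" is taken in its classical meaning: the
#' pooled-variance test (`var_equal = TRUE`); set `var_equal = FALSE` for
#' the Welch version. Experiment repetitions are pooled within genotype x
#' photoperiod by default; `by_repetition = TRUE` stratifies instead,
#' returning one contrast per repetition. No multiplicity adjustment is
#' applied.
#'
#' @param records Phenotype data.frame with `genotype`, `photoperiod_h`,
#'   `repetition` and `thermal_time_cd`.
#' @param pairs List of length-2 numeric vectors of photoperiods, default
#'   `list(c(16, 20), c(20, 22))`.
#' @param alpha Significance level for the flag column, default 0.05.
#' @param var_equal Pooled-variance test if `TRUE` (default).
#' @param by_repetition Stratify by experiment repetition, default `FALSE`.
#' @return data.frame with one row per genotype x pair (x repetition if
#'   stratified): group means, sample sizes, t statistic, degrees of
#'   freedom, p value, significance flag, and a `skipped_reason` column
#'   (non-`NA` when a contrast had fewer than 2 observations per arm and
#'   was skipped).
#' @examples
#' ph <- generate_phenotypes(design_spec(seed = 1))
#' head(photoperiod_contrasts(ph))
#' @export
photoperiod_contrasts <- function(records,
                                  pairs = list(c(16, 20), c(20, 22)),
                                  alpha = 0.05, var_equal = TRUE,
                                  by_repetition = FALSE) {
  stopifnot(all(c("genotype", "photoperiod_h", "thermal_time_cd")
                %in% names(records)))
  strata <- if (by_repetition) {
    split(records, list(records$genotype, records$repetition), drop = TRUE)
  } else {
    split(records, records$genotype)
  }
  rows <- list()
  for (sname in names(strata)) {
    sub <- strata[[sname]]
    g <- sub$genotype[1]
    rep_id <- if (by_repetition) sub$repetition[1] else NA_integer_
    for (pair in pairs) {
      a <- sub$thermal_time_cd[sub$photoperiod_h == pair[1]]
      b <- sub$thermal_time_cd[sub$photoperiod_h == pair[2]]
      base <- data.frame(
        genotype = g, repetition = rep_id,
        photoperiod_a = pair[1], photoperiod_b = pair[2],
        n_a = length(a), n_b = length(b),
        mean_a = if (length(a)) mean(a) else NA_real_,
        mean_b = if (length(b)) mean(b) else NA_real_,
        stringsAsFactors = FALSE
      )
      if (length(a) < 2 || length(b) < 2) {
        base$t_statistic <- NA_real_; base$df <- NA_real_
        base$p_value <- NA_real_; base$significant <- NA
        base$skipped_reason <- sprintf(
          "fewer than 2 observations per arm (n = %d vs %d)",
          length(a), length(b))
      } else {
        tt <- safe_t_test(a, b, var_equal)
        base$t_statistic <- tt$t
        base$df <- tt$df
        base$p_value <- tt$p
        base$significant <- tt$p < alpha
        base$skipped_reason <- NA_character_
      }
      rows[[length(rows) + 1L]] <- base
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$genotype, out$photoperiod_a, out$photoperiod_b), ]
  rownames(out) <- NULL
  if (!by_repetition) out$repetition <- NULL
  out
}

# Two-sample t-test that tolerates zero-variance data: identical constant
# groups carry no evidence against the null (t = 0, p = 1); constant
# groups with different means are infinitely separated (p = 0).
safe_t_test <- function(a, b, var_equal = TRUE) {
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    n <- length(a) + length(b) - 2
    if (mean(a) == mean(b)) return(list(t = 0, df = n, p = 1))
    return(list(t = sign(mean(a) - mean(b)) * Inf, df = n, p = 0))
  }
  tt <- stats::t.test(a, b, var.equal = var_equal)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}
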