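#' Collapse technical replicates to one Ct per biological replicate
#'
#' qPCR wells are run in technical duplicate; the biological replicate's Ct
#' is the mean over its detected technical replicates. If only some
#' technical replicates amplified, the bio rep keeps the detected mean and
#' is flagged `partial_detection`; if none amplified, the bio rep is
#' undetected.
#'
#' @param records Ct well data.frame (see [read_ct_table()] /
#'   [generate_ct_table()]).
#' @return data.frame with one row per gene x genotype x photoperiod x zt x
#'   bio_rep: `ct` (mean over detected tech reps or `NA`), `undetected`,
#'   `n_tech_detected`, `partial_detection`.
#' @export
collapse_tech_reps <- function(records) {
  validate_ct_table(records)
  key <- interaction(records$gene, records$genotype, records$photoperiod_h,
                     records$zt, records$bio_rep, drop = TRUE)
  rows <- lapply(split(records, key), function(sub) {
    det <- !sub$undetected
    data.frame(
      gene = sub$gene[1], genotype = sub$genotype[1],
      photoperiod_h = sub$photoperiod_h[1], zt = sub$zt[1],
      bio_rep = sub$bio_rep[1],
      ct = if (any(det)) mean(sub$ct[det]) else NA_real_,
      undetected = !any(det),
      n_tech_detected = sum(det),
      partial_detection = any(det) && any(!det),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$gene, out$genotype, out$photoperiod_h, out$zt,
                   out$bio_rep), ]
  rownames(out) <- NULL
  out
}

#' Relative expression by the delta-Ct method
#'
#' For each biological replicate of a target gene, relative expression is
#' \eqn{2^{-(Ct_{target} - Ct_{reference})}} against the reference gene
#' measured in the same (genotype, photoperiod, ZT, bio rep) sample. No
#' calibrator sample is used (delta-Ct, not delta-delta-Ct), so values are
#' expression relative to the reference gene. A value is computed only
#' when both target and reference amplified; otherwise the row is flagged
#' and the reason recorded (never silently dropped). Adding any constant
#' to every Ct in a sample (a plate-wide shift) leaves relative expression
#' unchanged.
#'
#' @param records Ct well data.frame; technical replicates are collapsed
#'   first via [collapse_tech_reps()] (already-collapsed tables pass
#'   through unchanged).
#' @param reference_gene Reference gene label, default `"HvTubA"`.
#' @return data.frame with one row per target-gene bio rep: `delta_ct`,
#'   `rel_expr` (\eqn{2^{-\Delta Ct}}, `NA` when not computable), `detected`
#'   flag and `omit_reason`.
#' @examples
#' eff <- data.frame(gene = c("HvTubA", "FT1"), genotype = "g",
#'                   photoperiod_h = 16, zt = 5, mean_ct = c(22, 23))
#' ct <- generate_ct_table(eff, sigma_bio = 0, sigma_tech = 0)
#' relative_expression(ct)$rel_expr  # 0.5, 0.5
#' @export
relative_expression <- function(records, reference_gene = "HvTubA") {
  bio <- if (!"tech_rep" %in% names(records)) records else
    collapse_tech_reps(records)
  if (!reference_gene %in% bio$gene) {
    stop("reference gene '", reference_gene, "' absent from the Ct table",
         call. = FALSE)
  }
  ref <- bio[bio$gene == reference_gene, ]
  tgt <- bio[bio$gene != reference_gene, ]
  key <- function(d) paste(d$genotype, d$photoperiod_h, d$zt, d$bio_rep,
                           sep = "\r")
  ref_ct <- ref$ct[match(key(tgt), key(ref))]
  ref_undet <- ref$undetected[match(key(tgt), key(ref))]
  delta <- tgt$ct - ref_ct
  omit <- ifelse(is.na(ref_ct) & is.na(ref_undet),
                 "reference well missing",
          ifelse(!is.na(ref_undet) & ref_undet, "reference undetected",
          ifelse(tgt$undetected, "target undetected", NA_character_)))
  data.frame(
    gene = tgt$gene, genotype = tgt$genotype,
    photoperiod_h = tgt$photoperiod_h, zt = tgt$zt, bio_rep = tgt$bio_rep,
    delta_ct = ifelse(is.na(omit), delta, NA_real_),
    rel_expr = ifelse(is.na(omit), 2^(-delta), NA_real_),
    detected = is.na(omit), omit_reason = omit,
    stringsAsFactors = FALSE
  )
}

#' Compare expression between genotypes per gene, time point and photoperiod
#'
#' Two-sided t-tests between genotype pairs within each gene x ZT x
#' photoperiod cell, run on log2 relative expression (equivalently
#' \eqn{-\Delta Ct}), where the Gaussian assumption is most defensible.
#' Cells with fewer than two detected biological replicates in either
#' group are reported as untestable with the reason, never silently
#' dropped.
#'
#' @param values Output of [relative_expression()].
#' @param genotype_pairs List of length-2 character vectors of genotype
#'   ids; default: all pairs present in `values`.
#' @param alpha Significance level for the flag column, default 0.05.
#' @param var_equal Pooled-variance test if `TRUE` (default).
#' @return data.frame: gene, photoperiod_h, zt, genotype pair, per-group
#'   detected counts and log2 means, t statistic, p value, significance
#'   flag, `testable`, and `untestable_reason`.
#' @export
compare_expression <- function(values, genotype_pairs = NULL, alpha = 0.05,
                               var_equal = TRUE) {
  if (is.null(genotype_pairs)) {
    gs <- sort(unique(values$genotype))
    genotype_pairs <- utils::combn(gs, 2, simplify = FALSE)
  }
  cells <- unique(values[c("gene", "photoperiod_h", "zt")])
  rows <- list()
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    sub <- values[values$gene == cell$gene &
                  values$photoperiod_h == cell$photoperiod_h &
                  values$zt == cell$zt, ]
    for (pair in genotype_pairs) {
      a <- sub[sub$genotype == pair[1] & sub$detected, "delta_ct"]
      b <- sub[sub$genotype == pair[2] & sub$detected, "delta_ct"]
      # t-test on -delta Ct == log2 relative expression
      a <- -a; b <- -b
      base <- data.frame(
        gene = cell$gene, photoperiod_h = cell$photoperiod_h, zt = cell$zt,
        genotype_a = pair[1], genotype_b = pair[2],
        n_a = length(a), n_b = length(b),
        log2_mean_a = if (length(a)) mean(a) else NA_real_,
        log2_mean_b = if (length(b)) mean(b) else NA_real_,
        stringsAsFactors = FALSE
      )
      if (length(a) < 2 || length(b) < 2) {
        base$t_statistic <- NA_real_; base$p_value <- NA_real_
        base$significant <- NA; base$testable <- FALSE
        base$untestable_reason <- sprintf(
          "fewer than 2 detected bio reps (n = %d vs %d)",
          length(a), length(b))
      } else {
        tt <- safe_t_test(a, b, var_equal)
        base$t_statistic <- tt$t
        base$p_value <- tt$p
        base$significant <- tt$p < alpha
        base$testable <- TRUE
        base$untestable_reason <- NA_character_
      }
      rows[[length(rows) + 1L]] <- base
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$gene, out$photoperiod_h, out$zt, out$genotype_a,
                   out$genotype_b), ]
  rownames(out) <- NULL
  out
}
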