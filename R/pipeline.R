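#' Assemble a pipeline run configuration
#'
#' One configuration drives the full analysis: simulate (or load)
#' phenotypes, fit and compare model variants, classify and recommend
#' photoperiods, run treatment contrasts, analyse qPCR expression, and
#' compute the lighting energy ledger. Every stochastic stage derives its
#' seed from the single `seed` field, so a configuration identifies its
#' outputs byte for byte.
#'
#' @param out_dir Output directory (created if absent).
#' @param seed Integer master seed.
#' @param stages Character vector of enabled stages, any of
#'   `"simulate"`, `"fit"`, `"contrasts"`, `"qpcr"`, `"energy"`.
#' @param phenotypes_path Optional CSV of real phenotypes; when set, the
#'   simulate stage is replaced by loading this file.
#' @param replicates,repetitions Design size for the simulate stage.
#' @param variants Model variants to compare, default
#'   `c("full", "shared_T", "flat")`.
#' @param contrast_pairs List of photoperiod pairs for the contrasts stage.
#' @param reference_gene qPCR reference gene, default `"HvTubA"`.
#' @param energy_reduced_h Reduced photoperiods to cost against the
#'   baseline, default `c(20, 16)`.
#' @param energy_baseline_h Baseline photoperiod, default 22.
#' @param facility_area_sqft Facility size for cost scaling, default 10000.
#' @return A list with class `"run_config"`.
#' @export
run_config <- function(out_dir, seed = 1L,
                       stages = c("simulate", "fit", "contrasts", "qpcr",
                                  "energy"),
                       phenotypes_path = NULL,
                       replicates = 5, repetitions = 2,
                       variants = c("full", "shared_T", "flat"),
                       contrast_pairs = list(c(16, 20), c(20, 22)),
                       reference_gene = "HvTubA",
                       energy_reduced_h = c(20, 16),
                       energy_baseline_h = 22,
                       facility_area_sqft = 10000) {
  stages <- match.arg(stages, several.ok = TRUE)
  structure(list(
    out_dir = out_dir, seed = as.integer(seed), stages = stages,
    phenotypes_path = phenotypes_path,
    replicates = replicates, repetitions = repetitions,
    variants = variants, contrast_pairs = contrast_pairs,
    reference_gene = reference_gene,
    energy_reduced_h = energy_reduced_h,
    energy_baseline_h = energy_baseline_h,
    facility_area_sqft = facility_area_sqft
  ), class = "run_config")
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file whose keys mirror the arguments of [run_config()]
#' (`contrast_pairs` as a list of two-element lists).
#'
#' @param path YAML file path.
#' @param out_dir Optional override of the configured output directory.
#' @return A `"run_config"` object.
#' @export
read_run_config <- function(path, out_dir = NULL) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$contrast_pairs)) {
    y$contrast_pairs <- lapply(y$contrast_pairs, unlist)
  }
  if (!is.null(out_dir)) y$out_dir <- out_dir
  do.call(run_config, y)
}

#' Run the full photoperiod-response pipeline
#'
#' Executes the enabled stages in order, writing per-stage artifacts
#' (CSV/JSON) plus a consolidated `report.md` into the configured output
#' directory. A stage failure is recorded with its message; stages that
#' depend on the failed one are skipped, independent stages still run.
#' Outputs contain no timestamps, so a re-run with an identical
#' configuration reproduces every file byte for byte.
#'
#' @param config A [run_config()] (or a YAML path accepted by
#'   [read_run_config()]).
#' @return Invisibly, the report bundle: a list with the per-stage results
#'   (`phenotypes`, `comparison`, `classification`, `contrasts`,
#'   `expression`, `expression_tests`, `energy`), the written `files`, a
#'   character vector of `warnings`, and `errors` (empty on success).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  bundle <- list(files = character(0), warnings = character(0),
                 errors = character(0))
  out_file <- function(name) file.path(config$out_dir, name)
  note_warn <- function(w) bundle$warnings <<- c(bundle$warnings, w)
  run_stage <- function(name, expr) {
    tryCatch(withCallingHandlers(expr, warning = function(w) {
      note_warn(sprintf("[%s] %s", name, conditionMessage(w)))
      invokeRestart("muffleWarning")
    }), error = function(e) {
      bundle$errors[name] <<- conditionMessage(e)
      NULL
    })
  }

  # -- phenotypes: simulate or load -----------------------------------
  phenotypes <- NULL
  if (!is.null(config$phenotypes_path)) {
    phenotypes <- run_stage("load_phenotypes",
                            read_phenotypes(config$phenotypes_path))
  } else if ("simulate" %in% config$stages) {
    phenotypes <- run_stage("simulate", {
      d <- design_spec(replicates = config$replicates,
                       repetitions = config$repetitions,
                       seed = config$seed)
      generate_phenotypes(d)
    })
  }
  if (!is.null(phenotypes)) {
    write_phenotypes(phenotypes, out_file("phenotypes.csv"))
    bundle$files <- c(bundle$files, out_file("phenotypes.csv"))
    bundle$phenotypes <- phenotypes
  }

  # -- model fitting, classification, recommendation ------------------
  if ("fit" %in% config$stages) {
    if (is.null(phenotypes)) {
      bundle$errors["fit"] <- "skipped: no phenotypes available"
    } else {
      cmp <- run_stage("fit",
        compare_variants(phenotypes, as.list(config$variants)))
      if (!is.null(cmp)) {
        bundle$comparison <- cmp
        best <- cmp$fits[[1]]
        # classification/recommendation read sensitivity intervals, so use
        # a variant that estimates S when the best-ranked one fixes it
        cls_fit <- if (best$variant$name != "flat") best else
          if (!is.null(cmp$fits[["full"]])) cmp$fits[["full"]] else best
        note_warn_fit <- cls_fit$warnings
        if (length(note_warn_fit)) note_warn(paste("[fit]", note_warn_fit))
        cls <- classify_response(cls_fit)
        rec <- recommend_photoperiod(cls)
        bundle$classification <- rec
        curves <- fitted_curve_table(cls_fit)
        utils::write.csv(curves, out_file("fitted_curves.csv"),
                         row.names = FALSE, quote = FALSE)
        fit_json <- list(
          variant_table = cmp$table, best_variant = cmp$best,
          estimates = cls_fit$estimates, classification = rec
        )
        jsonlite::write_json(fit_json, out_file("fit.json"),
                             auto_unbox = TRUE, digits = NA, na = "null")
        bundle$files <- c(bundle$files, out_file("fitted_curves.csv"),
                          out_file("fit.json"))
      }
    }
  }

  # -- treatment contrasts --------------------------------------------
  if ("contrasts" %in% config$stages) {
    if (is.null(phenotypes)) {
      bundle$errors["contrasts"] <- "skipped: no phenotypes available"
    } else {
      ctr <- run_stage("contrasts",
        photoperiod_contrasts(phenotypes, pairs = config$contrast_pairs))
      if (!is.null(ctr)) {
        bundle$contrasts <- ctr
        utils::write.csv(ctr, out_file("contrasts.csv"), row.names = FALSE)
        bundle$files <- c(bundle$files, out_file("contrasts.csv"))
      }
    }
  }

  # -- qPCR expression -------------------------------------------------
  if ("qpcr" %in% config$stages) {
    qp <- run_stage("qpcr", {
      ct <- generate_ct_table(default_ct_effects(),
                              seed = config$seed + 1L)
      vals <- relative_expression(ct, config$reference_gene)
      tests <- compare_expression(vals)
      list(ct = ct, values = vals, tests = tests)
    })
    if (!is.null(qp)) {
      bundle$expression <- qp$values
      bundle$expression_tests <- qp$tests
      write_ct_table(qp$ct, out_file("ct.csv"))
      utils::write.csv(qp$values, out_file("expression.csv"),
                       row.names = FALSE)
      utils::write.csv(qp$tests, out_file("expression_tests.csv"),
                       row.names = FALSE)
      bundle$files <- c(bundle$files, out_file("ct.csv"),
                        out_file("expression.csv"),
                        out_file("expression_tests.csv"))
      n_undet <- sum(qp$values$detected == FALSE)
      if (n_undet > 0) {
        note_warn(sprintf("[qpcr] %d expression values not computable (undetected wells)",
                          n_undet))
      }
    }
  }

  # -- energy ledger ----------------------------------------------------
  if ("energy" %in% config$stages) {
    en <- run_stage("energy", {
      lapply(config$energy_reduced_h, function(rh) {
        energy_report(energy_scenario(
          reduced_photoperiod_h = rh,
          baseline_photoperiod_h = config$energy_baseline_h,
          facility_area_sqft = config$facility_area_sqft))
      })
    })
    if (!is.null(en)) {
      names(en) <- sprintf("reduced_%gh", config$energy_reduced_h)
      bundle$energy <- en
      jsonlite::write_json(en, out_file("energy.json"),
                           auto_unbox = TRUE, digits = NA, na = "null")
      bundle$files <- c(bundle$files, out_file("energy.json"))
    }
  }

  report <- render_report(config, bundle)
  writeLines(report, out_file("report.md"))
  bundle$files <- c(bundle$files, out_file("report.md"))
  invisible(bundle)
}

# Plain-Markdown consolidated report; deliberately timestamp-free so that
# identical configurations produce identical bytes.
render_report <- function(config, bundle) {
  num <- function(x, d = 2) formatC(x, format = "f", digits = d)
  lines <- c(
    "# Photoperiod response pipeline report", "",
    "## Configuration", "",
    sprintf("- seed: %d", config$seed),
    sprintf("- stages: %s", paste(config$stages, collapse = ", ")),
    sprintf("- variants: %s", paste(config$variants, collapse = ", ")),
    ""
  )
  if (!is.null(bundle$phenotypes)) {
    lines <- c(lines, "## Phenotypes", "",
               sprintf("- %d plant records, %d genotypes, photoperiods %s h",
                       nrow(bundle$phenotypes),
                       length(unique(bundle$phenotypes$genotype)),
                       paste(sort(unique(bundle$phenotypes$photoperiod_h)),
                             collapse = "/")), "")
  }
  if (!is.null(bundle$comparison)) {
    tab <- bundle$comparison$table
    lines <- c(lines, "## Model fits", "",
      sprintf("Best variant: **%s** (%s)", bundle$comparison$best,
              bundle$comparison$criterion), "",
      "| variant | k | logLik | criterion | rank |",
      "|---|---|---|---|---|",
      sprintf("| %s | %d | %s | %s | %d |", tab$variant, tab$k,
              num(tab$logLik), num(tab[[4]]), tab$rank), "")
    cls <- bundle$classification
    lines <- c(lines,
      "### Classification and recommended photoperiods", "",
      "| genotype | class | S (degC d/h) | T (h) | recommended (h) |",
      "|---|---|---|---|---|",
      sprintf("| %s | %s | %s | %s | %g |", cls$genotype,
              cls$classification, num(cls$S),
              ifelse(is.na(cls$T), "NA", num(cls$T)), cls$recommended_h),
      "")
  }
  if (!is.null(bundle$contrasts)) {
    ctr <- bundle$contrasts
    lines <- c(lines, "## Photoperiod contrasts", "",
      "| genotype | pair | mean_a | mean_b | t | p | signif |",
      "|---|---|---|---|---|---|---|",
      sprintf("| %s | %gv%g | %s | %s | %s | %s | %s |",
              ctr$genotype, ctr$photoperiod_a, ctr$photoperiod_b,
              num(ctr$mean_a, 1), num(ctr$mean_b, 1),
              num(ctr$t_statistic), formatC(ctr$p_value, format = "g",
                                            digits = 3),
              ifelse(is.na(ctr$significant), "skipped",
                     ifelse(ctr$significant, "yes", "no"))), "")
  }
  if (!is.null(bundle$expression_tests)) {
    et <- bundle$expression_tests
    n_sig <- sum(et$significant %in% TRUE)
    n_unt <- sum(!et$testable)
    lines <- c(lines, "## Expression comparisons", "",
      sprintf("- %d genotype-pair tests; %d significant at 0.05; %d untestable (undetected-dominated cells)",
              nrow(et), n_sig, n_unt), "")
  }
  if (!is.null(bundle$energy)) {
    lines <- c(lines, "## Energy ledger", "",
      "| scenario | cut (%) | kWh/fixture/yr | facility cost/yr |",
      "|---|---|---|---|")
    for (nm in names(bundle$energy)) {
      e <- bundle$energy[[nm]]
      lines <- c(lines, sprintf("| %s | %d | %s | %s |", nm,
        e$fractional_saving_pct, num(e$annual_fixture_saving_kwh),
        if (is.null(e$facility_cost_saving)) "-" else
          num(e$facility_cost_saving)))
    }
    lines <- c(lines, "")
  }
  if (length(bundle$warnings)) {
    lines <- c(lines, "## Warnings", "",
               paste0("- ", bundle$warnings), "")
  }
  if (length(bundle$errors)) {
    lines <- c(lines, "## Stage errors", "",
               sprintf("- %s: %s", names(bundle$errors), bundle$errors), "")
  }
  lines
}
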