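#' Default generating parameters for the seven canonical genotypes
#'
#' An illustrative fixture of bi-linear response parameters qualitatively
#' matching the observed allele effects: genotypes carrying the recessive
#' \emph{ppd-H1} (Hv) allele respond with a 20-h threshold; genotypes with
#' the dominant \emph{Ppd-H1} (Hsp) allele and the \emph{elf3} mutant are
#' flat (already saturated at 16 h); the wild \emph{ELF3} (Hsp) allele
#' lowers intrinsic earliness in a \emph{ppd-H1} background; \emph{PhyC-e}
#' lowers photoperiod sensitivity. Magnitudes are stated assumptions, not
#' measured values; residual sigma defaults to 25 deg C d for every line.
#'
#' @param sigma Residual standard deviation applied to every genotype.
#' @return Named list of [response_params()], one per canonical genotype.
#' @export
default_response_params <- function(sigma = 25) {
  list(
    "ELF3_Hv/PPD-H1_Hv"   = response_params(I = 650, S = 45, T = 20, sigma = sigma),
    "ELF3_Hv/PPD-H1_Hsp"  = response_params(I = 560, S = 0,  T = NA, sigma = sigma),
    "ELF3_Hsp/PPD-H1_Hv"  = response_params(I = 600, S = 45, T = 20, sigma = sigma),
    "ELF3_Hsp/PPD-H1_Hsp" = response_params(I = 540, S = 0,  T = NA, sigma = sigma),
    "BW_WT"   = response_params(I = 620, S = 45, T = 20, sigma = sigma),
    "BW_ELF3" = response_params(I = 520, S = 0,  T = NA, sigma = sigma),
    "BW_PHYC" = response_params(I = 620, S = 30, T = 20, sigma = sigma)
  )
}

#' Specify a simulated growth-tent experiment
#'
#' Mirrors the real design: a set of genotypes, each with generating
#' response parameters, grown under a grid of photoperiods with `replicates`
#' plants per condition in each of `repetitions` experiment runs at a
#' constant 20 deg C.
#'
#' @param genotypes data.frame of genotype specs (default
#'   [canonical_genotypes()]); must have an `id` column.
#' @param params Named list of [response_params()] keyed by genotype id
#'   (default [default_response_params()]).
#' @param photoperiods_h Photoperiods in hours, default `c(16, 18, 20, 22, 24)`.
#' @param replicates Plants per genotype x photoperiod x repetition, default 5.
#' @param repetitions Experiment runs, default 2.
#' @param seed Integer RNG seed.
#' @param repetition_shift Additive deg C d offset applied to repetition 2
#'   (a run/year effect), default 0.
#' @return A list with class `"design_spec"`.
#' @export
design_spec <- function(genotypes = canonical_genotypes(),
                        params = default_response_params(),
                        photoperiods_h = c(16, 18, 20, 22, 24),
                        replicates = 5, repetitions = 2,
                        seed = 1L, repetition_shift = 0) {
  stopifnot(is.data.frame(genotypes), "id" %in% names(genotypes))
  stopifnot(replicates >= 1, repetitions >= 1)
  if (any(photoperiods_h < 0 | photoperiods_h > 24)) {
    stop("photoperiods must lie within [0, 24] hours", call. = FALSE)
  }
  missing <- setdiff(genotypes$id, names(params))
  if (length(missing)) {
    stop("no response parameters for genotype(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (id in genotypes$id) {
    if (params[[id]]$sigma <= 0) {
      stop("sigma must be > 0 for genotype ", id, call. = FALSE)
    }
  }
  structure(list(genotypes = genotypes, params = params,
                 photoperiods_h = photoperiods_h, replicates = replicates,
                 repetitions = repetitions, seed = as.integer(seed),
                 repetition_shift = repetition_shift),
            class = "design_spec")
}

#' Simulate plant phenotype records from a design
#'
#' Each plant's thermal time to heading is drawn as
#' `I + S * max(0, T - P) + shift * [repetition == 2] + eps`, with
#' `eps ~ Normal(0, sigma^2)` and the result truncated below at 1 deg C d
#' (flowering time cannot be non-positive). Days to heading are derived
#' assuming the design's constant 20 deg C. The draw order is fixed, so a
#' given seed reproduces the table exactly.
#'
#' @param design A [design_spec()].
#' @return data.frame in the phenotype schema, one row per plant;
#'   `|genotypes| x |photoperiods| x replicates x repetitions` rows.
#' @examples
#' d <- design_spec(seed = 42)
#' ph <- generate_phenotypes(d)
#' nrow(ph)  # 350
#' @export
generate_phenotypes <- function(design) {
  stopifnot(inherits(design, "design_spec"))
  set.seed(design$seed)
  g <- design$genotypes
  grid <- expand.grid(
    replicate = seq_len(design$replicates),
    photoperiod_h = design$photoperiods_h,
    repetition = seq_len(design$repetitions),
    genotype = g$id,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  idx <- match(grid$genotype, g$id)
  pars <- design$params[grid$genotype]
  I <- vapply(pars, `[[`, numeric(1), "I")
  S <- vapply(pars, `[[`, numeric(1), "S")
  T <- vapply(pars, `[[`, numeric(1), "T")
  sigma <- vapply(pars, `[[`, numeric(1), "sigma")
  hinge <- ifelse(S == 0, 0, S * pmax(0, T - grid$photoperiod_h))
  mu <- I + hinge + design$repetition_shift * (grid$repetition == 2)
  tt <- pmax(1, mu + stats::rnorm(nrow(grid), 0, sigma))
  out <- data.frame(
    genotype = grid$genotype,
    group = g$group[idx], elf3 = g$elf3[idx], ppdh1 = g$ppdh1[idx],
    phyc = g$phyc[idx],
    photoperiod_h = grid$photoperiod_h,
    replicate = grid$replicate, repetition = grid$repetition,
    days_to_heading = round(tt / 20, 2),  # constant 20 degC: 20 degC d/day
    thermal_time_cd = tt,
    stringsAsFactors = FALSE
  )
  validate_phenotypes(out)
  out
}

#' Simulate a constant-setpoint temperature log
#'
#' Readings every `cadence_min` minutes (48/day at the default 30-min
#' cadence), drawn as `Normal(mean_c, sd_c^2)`; `sd_c = 0` yields a constant
#' log at the setpoint.
#'
#' @param days Number of whole days (>= 1).
#' @param mean_c Setpoint in deg C, default 20.
#' @param sd_c Reading-to-reading SD in deg C, default 0.
#' @param cadence_min Minutes between readings, default 30.
#' @param seed Integer RNG seed.
#' @param origin First timestamp (POSIXct, UTC midnight by default).
#' @return data.frame with `timestamp` and `temp_c`.
#' @export
generate_temperature_log <- function(days, mean_c = 20, sd_c = 0,
                                     cadence_min = 30, seed = 1L,
                                     origin = as.POSIXct("2023-03-01 00:00:00",
                                                         tz = "UTC")) {
  stopifnot(days >= 1, cadence_min > 0, sd_c >= 0)
  set.seed(as.integer(seed))
  n_per_day <- as.integer(24 * 60 / cadence_min)
  n <- days * n_per_day
  ts <- origin + (seq_len(n) - 1L) * cadence_min * 60
  temp <- if (sd_c == 0) rep(mean_c, n) else stats::rnorm(n, mean_c, sd_c)
  data.frame(timestamp = ts, temp_c = temp)
}

#' Simulate a qPCR Ct table
#'
#' Generates one well per gene x genotype x photoperiod x ZT x biological x
#' technical replicate. True mean Ct values (and optionally a per-cell
#' undetected probability) come from the `effects` table; wells are drawn as
#' `mean + b + e` with a biological-replicate effect `b ~ N(0, sigma_bio^2)`
#' shared by a bio rep's technical duplicates and technical noise
#' `e ~ N(0, sigma_tech^2)`. Each well is independently flagged undetected
#' with its cell's probability, mimicking low-expression dropout.
#'
#' @param effects data.frame with columns `gene`, `genotype`,
#'   `photoperiod_h`, `zt`, `mean_ct` and optionally `p_undetected`
#'   (default 0).
#' @param bio_reps,tech_reps Replicate counts, default 2 and 2.
#' @param sigma_bio,sigma_tech Variance components (SD scale, cycles).
#' @param seed Integer RNG seed.
#' @return data.frame in the Ct schema.
#' @export
generate_ct_table <- function(effects, bio_reps = 2, tech_reps = 2,
                              sigma_bio = 0.3, sigma_tech = 0.15,
                              seed = 1L) {
  need <- c("gene", "genotype", "photoperiod_h", "zt", "mean_ct")
  missing <- setdiff(need, names(effects))
  if (length(missing)) {
    stop("effects table missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (is.null(effects$p_undetected)) effects$p_undetected <- 0
  if (any(effects$p_undetected < 0 | effects$p_undetected > 1)) {
    stop("p_undetected must lie in [0, 1]", call. = FALSE)
  }
  set.seed(as.integer(seed))
  rows <- vector("list", nrow(effects))
  for (i in seq_len(nrow(effects))) {
    e <- effects[i, ]
    b <- stats::rnorm(bio_reps, 0, sigma_bio)
    cell <- expand.grid(tech_rep = seq_len(tech_reps),
                        bio_rep = seq_len(bio_reps),
                        KEEP.OUT.ATTRS = FALSE)
    ct <- e$mean_ct + b[cell$bio_rep] +
      stats::rnorm(nrow(cell), 0, sigma_tech)
    undet <- stats::runif(nrow(cell)) < e$p_undetected
    rows[[i]] <- data.frame(
      gene = e$gene, genotype = e$genotype,
      photoperiod_h = e$photoperiod_h, zt = e$zt,
      bio_rep = cell$bio_rep, tech_rep = cell$tech_rep,
      ct = ifelse(undet, NA_real_, ct), undetected = undet,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  validate_ct_table(out)
  out
}

#' Illustrative qPCR expression effects for the HEB group
#'
#' A default `effects` table for [generate_ct_table()] emulating the
#' observed pattern: the reference gene (HvTubA) stable everywhere;
#' PPD-H1 transcript more abundant (lower Ct) in lines carrying the
#' dominant Ppd-H1 (Hsp) allele; FT1 following PPD-H1 with dropout
#' (undetected wells) in the low-expressing Hv/Hv line. Values are
#' illustrative assumptions, not measured means.
#'
#' @param photoperiods_h Photoperiods sampled, default `c(16, 22)`.
#' @param zts Zeitgeber times, default `c(5, 11, 17, 23)`.
#' @return data.frame usable as `effects` in [generate_ct_table()].
#' @export
default_ct_effects <- function(photoperiods_h = c(16, 22),
                               zts = c(5, 11, 17, 23)) {
  heb <- canonical_genotypes()
  heb <- heb[heb$group == "HEB", ]
  grid <- expand.grid(gene = c("HvTubA", "PPD-H1", "FT1"),
                      genotype = heb$id, photoperiod_h = photoperiods_h,
                      zt = zts, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  hsp <- grepl("PPD-H1_Hsp", grid$genotype)
  mean_ct <- ifelse(grid$gene == "HvTubA", 22,
             ifelse(grid$gene == "PPD-H1", ifelse(hsp, 26, 29),
                    ifelse(hsp, 27, 31)))  # FT1
  p_undet <- ifelse(grid$gene == "FT1" & !hsp & grid$photoperiod_h == 16,
                    0.5, 0)
  cbind(grid, mean_ct = mean_ct, p_undetected = p_undet)
}
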