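#' @name photothermal-io
#' @title CSV readers and writers
#'
#' @description
#' All tables travel as comma-separated UTF-8 files with a mandatory header
#' row, "." as the decimal separator, and a schema-version comment
#' (`#schema=photothermal-v1`) as the first line. Three schemas are used:
#'
#' * phenotypes: `genotype,group,elf3,ppdh1,phyc,photoperiod_h,replicate,
#'   repetition,days_to_heading,thermal_time_cd`
#' * temperature: `timestamp_iso8601,temp_c`
#' * Ct wells: `gene,genotype,photoperiod_h,zt,bio_rep,tech_rep,ct,undetected`
#'
#' Readers validate every row and fail loudly with the offending column or
#' line number; writers round-trip losslessly.
NULL

SCHEMA_LINE <- "#schema=photothermal-v1"

phenotype_cols <- c("genotype", "group", "elf3", "ppdh1", "phyc",
                    "photoperiod_h", "replicate", "repetition",
                    "days_to_heading", "thermal_time_cd")

read_schema_csv <- function(path, required_cols, what) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  skip <- if (startsWith(first, "#")) 1L else 0L
  df <- utils::read.csv(path, skip = skip, stringsAsFactors = FALSE)
  missing <- setdiff(required_cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s schema error: missing column(s) %s in %s",
                 what, paste(missing, collapse = ", "), path), call. = FALSE)
  }
  df
}

write_schema_csv <- function(df, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(SCHEMA_LINE, con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate a table of plant records
#'
#' Checks the invariants of one plant's record: photoperiod within
#' \eqn{[0, 24]} hours (light + dark = 24 h), positive replicate and
#' repetition indices, non-negative days to heading where present, and a
#' finite non-negative thermal time to heading for every analysed record
#' (days to heading may be absent when thermal time is supplied directly).
#'
#' @param records data.frame in the phenotype schema.
#' @return The validated data.frame, invisibly unchanged.
#' @export
validate_phenotypes <- function(records) {
  stopifnot(is.data.frame(records))
  missing <- setdiff(phenotype_cols, names(records))
  if (length(missing)) {
    stop("phenotype schema error: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  pp <- records$photoperiod_h
  if (!is.numeric(pp)) {
    bad <- which(is.na(suppressWarnings(as.numeric(pp))))[1]
    stop(sprintf("non-numeric photoperiod_h at row %d", bad), call. = FALSE)
  }
  bad <- which(!is.finite(pp) | pp < 0 | pp > 24)
  if (length(bad)) {
    stop(sprintf("photoperiod_h outside [0, 24] at row %d (value %s)",
                 bad[1], pp[bad[1]]), call. = FALSE)
  }
  if (any(records$replicate < 1) || any(records$repetition < 1)) {
    stop("replicate and repetition indices must be >= 1", call. = FALSE)
  }
  tt <- records$thermal_time_cd
  bad <- which(!is.finite(tt) | tt < 0)
  if (length(bad)) {
    stop(sprintf("thermal_time_cd missing or negative at row %d", bad[1]),
         call. = FALSE)
  }
  d <- records$days_to_heading
  bad <- which(!is.na(d) & d < 0)
  if (length(bad)) {
    stop(sprintf("days_to_heading negative at row %d", bad[1]), call. = FALSE)
  }
  invisible(records)
}

#' Read and write plant phenotype tables
#'
#' @param path CSV file path.
#' @return `read_phenotypes`: a validated data.frame of plant records, one
#'   row per plant.
#' @seealso [validate_phenotypes()] for the row-level invariants.
#' @export
read_phenotypes <- function(path) {
  df <- read_schema_csv(path, phenotype_cols, "phenotype")
  if (!is.numeric(df$photoperiod_h)) {
    bad <- which(is.na(suppressWarnings(as.numeric(df$photoperiod_h))))[1]
    stop(sprintf("non-numeric photoperiod_h at line %d of %s",
                 bad + 2L, path), call. = FALSE)
  }
  validate_phenotypes(df)
  df
}

#' @rdname read_phenotypes
#' @param records data.frame in the phenotype schema.
#' @export
write_phenotypes <- function(records, path) {
  validate_phenotypes(records)
  write_schema_csv(records[phenotype_cols], path)
}

#' Read and write temperature logs
#'
#' A temperature log is an ordered series of (timestamp, temperature)
#' readings, nominally at a 30-minute cadence, used for thermal-time
#' accumulation. Timestamps must be strictly increasing and temperatures
#' finite.
#'
#' @param path CSV file path (`timestamp_iso8601,temp_c`).
#' @return `read_temperature_log`: a data.frame with POSIXct `timestamp`
#'   (UTC) and numeric `temp_c`.
#' @export
read_temperature_log <- function(path) {
  df <- read_schema_csv(path, c("timestamp_iso8601", "temp_c"), "temperature")
  ts <- as.POSIXct(df$timestamp_iso8601, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S"))
  if (anyNA(ts)) {
    stop(sprintf("unparseable timestamp at line %d of %s",
                 which(is.na(ts))[1] + 2L, path), call. = FALSE)
  }
  out <- data.frame(timestamp = ts, temp_c = as.numeric(df$temp_c))
  validate_temperature_log(out)
  out
}

#' @rdname read_temperature_log
#' @param log data.frame with `timestamp` (POSIXct) and `temp_c` columns.
#' @export
write_temperature_log <- function(log, path) {
  validate_temperature_log(log)
  df <- data.frame(
    timestamp_iso8601 = format(log$timestamp, "%Y-%m-%dT%H:%M:%S",
                               tz = "UTC"),
    temp_c = log$temp_c
  )
  write_schema_csv(df, path)
}

validate_temperature_log <- function(log) {
  stopifnot(is.data.frame(log), all(c("timestamp", "temp_c") %in% names(log)))
  if (nrow(log) == 0) stop("empty temperature log", call. = FALSE)
  if (any(diff(as.numeric(log$timestamp)) <= 0)) {
    stop("temperature log timestamps must be strictly increasing",
         call. = FALSE)
  }
  if (any(!is.finite(log$temp_c))) {
    stop("temperature log contains non-finite temperatures", call. = FALSE)
  }
  invisible(log)
}

ct_cols <- c("gene", "genotype", "photoperiod_h", "zt", "bio_rep",
             "tech_rep", "ct", "undetected")

#' Read and write qPCR Ct tables
#'
#' One row per well: target or reference gene, genotype, photoperiod,
#' Zeitgeber time (hours after lights-on), biological and technical
#' replicate indices, and either a Ct value (> 0 cycles) or an undetected
#' flag. Undetected wells carry no Ct value.
#'
#' @param path CSV file path.
#' @return `read_ct_table`: a validated data.frame of Ct well records.
#' @export
read_ct_table <- function(path) {
  df <- read_schema_csv(path, ct_cols, "ct")
  df$undetected <- as.logical(df$undetected)
  df$ct <- suppressWarnings(as.numeric(df$ct))
  validate_ct_table(df)
  df
}

#' @rdname read_ct_table
#' @param records data.frame in the Ct schema.
#' @export
write_ct_table <- function(records, path) {
  validate_ct_table(records)
  out <- records[ct_cols]
  out$ct <- ifelse(out$undetected, "", format(out$ct, trim = TRUE))
  write_schema_csv(out, path)
}

validate_ct_table <- function(records) {
  stopifnot(is.data.frame(records))
  missing <- setdiff(ct_cols, names(records))
  if (length(missing)) {
    stop("ct schema error: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad <- which(!records$undetected & (!is.finite(records$ct) | records$ct <= 0))
  if (length(bad)) {
    stop(sprintf("detected well without positive ct at row %d", bad[1]),
         call. = FALSE)
  }
  if (any(records$undetected & !is.na(records$ct))) {
    stop("undetected wells must not carry a ct value", call. = FALSE)
  }
  invisible(records)
}
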