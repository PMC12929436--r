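#' Genotype specifications
#'
#' Constructors and validators for the genotype metadata used throughout the
#' package. A genotype is described by its group (a HEB-25 derived recombinant
#' inbred panel, or a Bowman near-isogenic panel) and its alleles at three
#' flowering-time loci: \emph{ELF3}, \emph{PPD-H1} and \emph{PHYC}.
#'
#' Allele coding:
#' \itemize{
#'   \item \code{elf3_allele}: \code{"Hv"} (domesticated), \code{"Hsp"}
#'     (wild), or \code{"elf3_mutant"} (loss-of-function, photoperiod
#'     insensitive).
#'   \item \code{ppdh1_allele}: \code{"Hv"} (recessive \emph{ppd-H1},
#'     photoperiod responsive in the long-day range) or \code{"Hsp"}
#'     (dominant \emph{Ppd-H1}, saturated below 16 h).
#'   \item \code{phyc_allele}: \code{"PhyC_I"} or \code{"PhyC_e"}.
#' }
#'
#' @param id Short genotype label.
#' @param group \code{"HEB"} or \code{"Bowman"}.
#' @param elf3_allele,ppdh1_allele,phyc_allele Allele codes, see Details.
#' @return A one-row data.frame with class \code{"genotype_spec"} attached.
#' @examples
#' genotype_spec("BW_WT", "Bowman", "Hsp", "Hv", "PhyC_I")
#' @export
genotype_spec <- function(id, group, elf3_allele, ppdh1_allele,
                          phyc_allele = "PhyC_I") {
  group <- match.arg(group, c("HEB", "Bowman"))
  elf3_allele <- match.arg(elf3_allele, c("Hv", "Hsp", "elf3_mutant"))
  ppdh1_allele <- match.arg(ppdh1_allele, c("Hv", "Hsp"))
  phyc_allele <- match.arg(phyc_allele, c("PhyC_I", "PhyC_e"))
  if (group == "Bowman" && ppdh1_allele != "Hv") {
    stop("Bowman-group genotypes share the recessive ppd-H1 (Hv) background",
         call. = FALSE)
  }
  out <- data.frame(
    id = as.character(id), group = group, elf3 = elf3_allele,
    ppdh1 = ppdh1_allele, phyc = phyc_allele, stringsAsFactors = FALSE
  )
  class(out) <- c("genotype_spec", class(out))
  out
}

#' The seven canonical genotypes of the growth-tent experiment
#'
#' Four HEB lines carrying the factorial combinations of \emph{ELF3} and
#' \emph{PPD-H1} alleles, plus the Bowman wild type and its \emph{elf3} and
#' \emph{PhyC-e} near-isogenic lines.
#'
#' @return A seven-row data.frame of genotype specifications.
#' @export
canonical_genotypes <- function() {
  g <- rbind(
    genotype_spec("ELF3_Hv/PPD-H1_Hv",   "HEB",    "Hv",  "Hv"),
    genotype_spec("ELF3_Hv/PPD-H1_Hsp",  "HEB",    "Hv",  "Hsp"),
    genotype_spec("ELF3_Hsp/PPD-H1_Hv",  "HEB",    "Hsp", "Hv"),
    genotype_spec("ELF3_Hsp/PPD-H1_Hsp", "HEB",    "Hsp", "Hsp"),
    genotype_spec("BW_WT",   "Bowman", "Hsp",         "Hv", "PhyC_I"),
    genotype_spec("BW_ELF3", "Bowman", "elf3_mutant", "Hv", "PhyC_I"),
    genotype_spec("BW_PHYC", "Bowman", "Hsp",         "Hv", "PhyC_e")
  )
  class(g) <- c("genotype_spec", "data.frame")
  g
}

#' Bi-linear photoperiod-response parameters
#'
#' The quadruple that defines one genotype's flowering-time response to
#' photoperiod: intrinsic earliness \code{I} (the plateau, in degree-days),
#' photoperiod sensitivity \code{S} (degree-days of delay per hour of day
#' length below the threshold), threshold photoperiod \code{T} (hours), and
#' the residual standard deviation \code{sigma} (degree-days).
#'
#' The implied mean thermal time to heading at photoperiod \code{P} is
#' \code{I + S * max(0, T - P)}: non-increasing in \code{P} and equal to
#' \code{I} for all photoperiods at or beyond the threshold.
#'
#' @param I Intrinsic earliness, degree-days (> 0).
#' @param S Photoperiod sensitivity, degree-days per hour (>= 0).
#' @param T Threshold photoperiod, hours; must lie within \code{t_bounds}.
#'   Ignored (may be \code{NA}) when \code{S = 0}.
#' @param sigma Residual standard deviation, degree-days (> 0).
#' @param t_bounds Admissible threshold range, default \code{c(12, 24)}.
#' @return A list with class \code{"response_params"}.
#' @examples
#' p <- response_params(I = 600, S = 50, T = 20, sigma = 10)
#' predict_mean(p, 16)  # 800
#' @export
response_params <- function(I, S, T, sigma, t_bounds = c(12, 24)) {
  stopifnot(is.numeric(I), length(I) == 1, is.finite(I), I > 0)
  stopifnot(is.numeric(S), length(S) == 1, is.finite(S), S >= 0)
  stopifnot(is.numeric(sigma), length(sigma) == 1, is.finite(sigma),
            sigma > 0)
  if (S == 0) {
    T <- NA_real_
  } else {
    stopifnot(is.numeric(T), length(T) == 1, is.finite(T))
    if (T < t_bounds[1] || T > t_bounds[2]) {
      stop(sprintf("threshold T = %g outside bounds [%g, %g]",
                   T, t_bounds[1], t_bounds[2]), call. = FALSE)
    }
  }
  structure(list(I = I, S = S, T = T, sigma = sigma),
            class = "response_params")
}

#' @export
print.response_params <- function(x, ...) {
  cat(sprintf(
    "Photoperiod response: I = %.1f degC d, S = %.2f degC d/h, T = %s h, sigma = %.2f\n",
    x$I, x$S, if (is.na(x$T)) "NA (flat)" else sprintf("%.2f", x$T), x$sigma))
  invisible(x)
}
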