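# Shared fixtures and the independent grid-search oracle for the hinge fit.

# One-genotype record table drawn from the bi-linear truth.
make_records <- function(I, S, T, sigma, n_per_p = 10,
                         photoperiods = c(16, 18, 20, 22, 24),
                         genotype = "g", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  P <- rep(photoperiods, each = n_per_p)
  mu <- if (S == 0) rep(I, length(P)) else I + S * pmax(0, T - P)
  data.frame(genotype = genotype, photoperiod_h = P,
             replicate = seq_along(P), repetition = 1L,
             thermal_time_cd = mu + stats::rnorm(length(P), 0, sigma),
             stringsAsFactors = FALSE)
}

# Independent oracle: exhaustive grid over the threshold with lm() solving
# the least-squares (I, S) at each candidate, then continuous refinement of
# the same lm-based objective. Shares no code with the package's fitter.
oracle_hinge_fit <- function(P, y, t_bounds = c(12, 24), coarse = 0.1) {
  eval_T <- function(Tg) {
    x <- pmax(0, Tg - P)
    if (stats::var(x) > 0) {
      m <- stats::lm(y ~ x)
      s <- unname(stats::coef(m)[2]); i0 <- unname(stats::coef(m)[1])
      if (s < 0) { s <- 0; i0 <- mean(y) }
    } else {
      s <- 0; i0 <- mean(y)
    }
    list(sse = sum((y - i0 - s * x)^2), I = i0, S = s)
  }
  grid <- seq(t_bounds[1], t_bounds[2], by = coarse)
  sse <- vapply(grid, function(Tg) eval_T(Tg)$sse, numeric(1))
  k <- which.min(sse)
  op <- stats::optimize(function(Tg) eval_T(Tg)$sse,
                        c(grid[max(1, k - 1)], grid[min(length(grid), k + 1)]))
  Tb <- if (op$objective < sse[k]) op$minimum else grid[k]
  c(eval_T(Tb)[c("I", "S")], T = Tb)
}

# Minimal valid phenotype table in the full CSV schema.
tiny_phenotypes <- function() {
  data.frame(
    genotype = c("BW_WT", "BW_WT", "BW_ELF3"),
    group = c("Bowman", "Bowman", "Bowman"),
    elf3 = c("Hsp", "Hsp", "elf3_mutant"),
    ppdh1 = "Hv", phyc = "PhyC_I",
    photoperiod_h = c(16, 20, 16),
    replicate = c(1, 1, 1), repetition = c(1, 1, 1),
    days_to_heading = c(40, 31, 26.5),
    thermal_time_cd = c(800, 620, 530),
    stringsAsFactors = FALSE
  )
}
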