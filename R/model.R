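#' Mean thermal time to heading under the bi-linear photoperiod model
#'
#' The linear-plateau (hinge) mean function
#' \deqn{\mu(P) = I + S \cdot \max(0, T - P)}
#' an initial linear decline in flowering time as photoperiod lengthens,
#' with slope magnitude \code{S} (photoperiod sensitivity), until the
#' threshold photoperiod \code{T}, beyond which flowering time plateaus at
#' the intrinsic earliness \code{I}. The mean is non-increasing in \code{P}
#' and constant at \code{I} for all \code{P >= T}.
#'
#' @param params A [response_params()] object (for \code{S = 0} the
#'   threshold is irrelevant and the mean is flat at \code{I}).
#' @param P Photoperiod(s) in hours, each in \eqn{[0, 24]}.
#' @return Predicted mean thermal time(s) in degree-days.
#' @examples
#' predict_mean(response_params(600, 50, 20, 10), c(16, 22))  # 800, 600
#' @export
predict_mean <- function(params, P) {
  stopifnot(inherits(params, "response_params"))
  if (any(!is.finite(P) | P < 0 | P > 24)) {
    stop("photoperiod P must lie in [0, 24] hours", call. = FALSE)
  }
  if (params$S == 0) return(rep(params$I, length(P)))
  params$I + params$S * pmax(0, params$T - P)
}

#' Model variants for joint fitting
#'
#' A variant names which of the response parameters are estimated per
#' genotype, which are shared across genotypes, and which are fixed:
#' \describe{
#'   \item{full}{per-genotype intrinsic earliness, sensitivity, threshold
#'     and residual SD (4 parameters per genotype).}
#'   \item{shared_T}{per-genotype I, S and sigma, one threshold common to
#'     all genotypes (3 per genotype + 1).}
#'   \item{flat}{sensitivity fixed at zero; the threshold drops out and
#'     each genotype is described by its mean and SD (2 per genotype).}
#' }
#'
#' @param name `"full"`, `"shared_T"` or `"flat"`.
#' @param t_bounds Admissible threshold range in hours, default
#'   `c(12, 24)`. The experiment informs the threshold only inside the
#'   tested photoperiod range; estimates at the bounds are flagged.
#' @return A list with class `"model_variant"`.
#' @export
model_variant <- function(name = c("full", "shared_T", "flat"),
                          t_bounds = c(12, 24)) {
  name <- match.arg(name)
  sharing <- switch(name,
    full     = list(I = "per_genotype", S = "per_genotype",
                    T = "per_genotype", sigma = "per_genotype"),
    shared_T = list(I = "per_genotype", S = "per_genotype",
                    T = "shared", sigma = "per_genotype"),
    flat     = list(I = "per_genotype", S = "fixed_zero",
                    T = "dropped", sigma = "per_genotype")
  )
  structure(list(name = name, sharing = sharing, t_bounds = t_bounds),
            class = "model_variant")
}

# Constrained least squares of y on the hinge basis max(0, T - P) for a
# fixed threshold T, with the sensitivity constrained to S >= 0 (the
# response cannot slow down as days lengthen). Closed form; returns the
# profiled I, S and residual sum of squares.
hinge_ls <- function(P, y, T) {
  x <- pmax(0, T - P)
  n <- length(y)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  if (sxx > 0) {
    s <- sum((x - mx) * (y - my)) / sxx
    if (s < 0) s <- 0
  } else {
    s <- 0
  }
  i <- my - s * mx
  res <- y - i - s * x
  list(I = i, S = s, sse = sum(res^2))
}

# Profile the threshold for one genotype (or, for shared_T, pool the
# per-genotype SSE curves): coarse grid then golden-section refinement of
# the continuous profile around the grid optimum.
profile_threshold <- function(sse_fun, t_bounds, step = 0.1) {
  grid <- seq(t_bounds[1], t_bounds[2], by = step)
  sse <- vapply(grid, sse_fun, numeric(1))
  k <- which.min(sse)
  lo <- grid[max(1, k - 1)]
  hi <- grid[min(length(grid), k + 1)]
  ref <- stats::optimize(sse_fun, interval = c(lo, hi))
  if (ref$objective < sse[k]) {
    list(T = ref$minimum, sse = ref$objective)
  } else {
    list(T = grid[k], sse = sse[k])
  }
}

# Linearised standard errors at the optimum: Jacobian columns are the
# partial derivatives of the mean in (I, S, T); for a flat solution the
# slope SE is evaluated on a full-range hinge so that "slope
# indistinguishable from zero" is assessed over the tested photoperiods.
hinge_se <- function(P, y, I, S, T, flat = FALSE) {
  n <- length(y)
  if (flat || S == 0) {
    T_ref <- if (!is.na(T) && stats::var(pmax(0, T - P)) > 0) T else max(P)
    x <- pmax(0, T_ref - P)
    J <- cbind(1, x)
    k <- 2
    res <- y - mean(y)
  } else {
    x <- pmax(0, T - P)
    J <- cbind(1, x, S * (P < T))
    k <- 3
    res <- y - I - S * x
  }
  df <- max(n - k, 1)
  s2 <- sum(res^2) / df
  V <- tryCatch(s2 * solve(crossprod(J)), error = function(e) NULL)
  if (is.null(V)) {
    se <- rep(NA_real_, 3)
  } else {
    se <- sqrt(diag(V))
    if (ncol(J) == 2) se <- c(se, NA_real_)
  }
  names(se) <- c("I", "S", "T")
  se
}

#' Fit the bi-linear photoperiod response model
#'
#' Deterministic maximum-likelihood fitting under Gaussian residuals with
#' per-genotype residual SD. The threshold enters non-linearly, so the fit
#' profiles it: for each candidate threshold the intrinsic earliness and
#' sensitivity have a closed-form least-squares solution (with \eqn{S \ge 0}
#' enforced); a coarse grid over the admissible threshold range is followed
#' by local refinement of the continuous profile. The procedure involves no
#' random numbers and is invariant to record order.
#'
#' Standard errors come from the usual nonlinear-least-squares
#' linearisation at the optimum; 95% intervals are Wald intervals. When the
#' profiled sensitivity is zero the threshold is not identifiable and is
#' reported as `NA` with a flag.
#'
#' @param records Phenotype data.frame (see [read_phenotypes()] /
#'   [generate_phenotypes()]); must contain `genotype`, `photoperiod_h`
#'   and `thermal_time_cd`.
#' @param variant A [model_variant()] or its name.
#' @param t_grid_step Grid resolution for the threshold profile, hours.
#' @param level Interval coverage, default 0.95.
#' @param criterion `"BIC"` (default) or `"AICc"`; both are computed, this
#'   selects which fills `information_criterion`.
#' @return An object of class `"photoperiod_fit"`: a list with `variant`,
#'   `estimates` (data.frame: genotype, parameter, estimate, se, lower,
#'   upper, plus flags), `logLik`, `n_obs`, `k` (parameter count), `BIC`,
#'   `AICc`, `information_criterion`, `converged`, `warnings`, and
#'   `fitted_curve`, a function `(genotype, P) ->` predicted degree-days.
#' @examples
#' d <- design_spec(seed = 7, replicates = 10)
#' fit <- fit_photoperiod_model(generate_phenotypes(d), "full")
#' head(fit$estimates)
#' @export
fit_photoperiod_model <- function(records, variant = "full",
                                  t_grid_step = 0.1, level = 0.95,
                                  criterion = c("BIC", "AICc")) {
  criterion <- match.arg(criterion)
  if (is.character(variant)) variant <- model_variant(variant)
  stopifnot(inherits(variant, "model_variant"))
  need <- c("genotype", "photoperiod_h", "thermal_time_cd")
  if (!all(need %in% names(records))) {
    stop("records must contain columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  records <- records[order(records$genotype, records$photoperiod_h,
                           records$thermal_time_cd), ]
  gids <- sort(unique(records$genotype))
  by_g <- split(records, records$genotype)[gids]
  tb <- variant$t_bounds
  warnings <- character(0)

  if (variant$name %in% c("full", "shared_T")) {
    for (g in gids) {
      if (length(unique(by_g[[g]]$photoperiod_h)) < 2) {
        stop(sprintf(paste0(
          "genotype %s observed at a single photoperiod: threshold and ",
          "sensitivity are not identifiable"), g), call. = FALSE)
      }
    }
  }

  est_row <- function(genotype, param, estimate, se, z) {
    data.frame(genotype = genotype, parameter = param,
               estimate = estimate, se = se,
               lower = estimate - z * se, upper = estimate + z * se,
               stringsAsFactors = FALSE)
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  per_g <- list()
  logLik <- 0

  # unclamped straight-line slope of thermal time on decreasing photoperiod
  # over the whole tested range; used by classify_response() to judge
  # whether a genotype's response is distinguishable from flat
  range_slope <- function(P, y) {
    sxx <- sum((P - mean(P))^2)
    if (sxx == 0) return(c(est = NA_real_, se = NA_real_))
    s <- -sum((P - mean(P)) * (y - mean(y))) / sxx
    res <- y - mean(y) - (-s) * (P - mean(P))
    se <- sqrt(sum(res^2) / max(length(y) - 2, 1) / sxx)
    c(est = s, se = se)
  }

  fill_genotype <- function(g, P, y, I, S, T, flat) {
    n <- length(y)
    x <- if (flat || S == 0) 0 else S * pmax(0, T - P)
    res <- y - I - x
    sse <- sum(res^2)
    sigma <- sqrt(sse / n)  # ML estimate
    se <- hinge_se(P, y, I, S, T, flat = flat)
    rows <- rbind(
      est_row(g, "I", I, se[["I"]], z),
      est_row(g, "S", S, se[["S"]], z),
      est_row(g, "T", if (flat) NA_real_ else T, se[["T"]], z),
      est_row(g, "sigma", sigma, NA_real_, z)
    )
    ll <- -n / 2 * (log(2 * pi * sigma^2) + 1)
    rs <- range_slope(P, y)
    list(rows = rows, logLik = ll, I = I, S = S,
         T = if (flat) NA_real_ else T, sigma = sigma,
         S_range = rs[["est"]], S_range_se = rs[["se"]])
  }

  if (variant$name == "flat") {
    for (g in gids) {
      P <- by_g[[g]]$photoperiod_h; y <- by_g[[g]]$thermal_time_cd
      per_g[[g]] <- fill_genotype(g, P, y, I = mean(y), S = 0, T = NA,
                                  flat = TRUE)
    }
  } else if (variant$name == "full") {
    for (g in gids) {
      P <- by_g[[g]]$photoperiod_h; y <- by_g[[g]]$thermal_time_cd
      prof <- profile_threshold(function(T) hinge_ls(P, y, T)$sse, tb,
                                t_grid_step)
      ls <- hinge_ls(P, y, prof$T)
      flat <- ls$S == 0
      if (flat) {
        warnings <- c(warnings, sprintf(
          "genotype %s: profiled sensitivity is zero; threshold not identifiable",
          g))
        per_g[[g]] <- fill_genotype(g, P, y, I = mean(y), S = 0, T = NA,
                                    flat = TRUE)
      } else {
        if (prof$T <= tb[1] + 1e-8 || prof$T >= tb[2] - 1e-8) {
          warnings <- c(warnings, sprintf(
            "genotype %s: threshold estimate at the bound of [%g, %g]",
            g, tb[1], tb[2]))
        }
        if (prof$T < min(P)) {
          warnings <- c(warnings, sprintf(
            "genotype %s: threshold below the tested photoperiod range (extrapolation)",
            g))
        }
        per_g[[g]] <- fill_genotype(g, P, y, ls$I, ls$S, prof$T, flat = FALSE)
      }
    }
  } else {  # shared_T
    pooled_sse <- function(T) {
      sum(vapply(gids, function(g) {
        hinge_ls(by_g[[g]]$photoperiod_h, by_g[[g]]$thermal_time_cd, T)$sse
      }, numeric(1)))
    }
    prof <- profile_threshold(pooled_sse, tb, t_grid_step)
    for (g in gids) {
      P <- by_g[[g]]$photoperiod_h; y <- by_g[[g]]$thermal_time_cd
      ls <- hinge_ls(P, y, prof$T)
      per_g[[g]] <- fill_genotype(g, P, y, ls$I, ls$S,
                                  if (ls$S == 0) NA else prof$T,
                                  flat = ls$S == 0)
    }
  }

  logLik <- sum(vapply(per_g, `[[`, numeric(1), "logLik"))
  n_obs <- nrow(records)
  G <- length(gids)
  k <- switch(variant$name, full = 4 * G, flat = 2 * G, shared_T = 3 * G + 1)
  BIC <- -2 * logLik + k * log(n_obs)
  AICc <- -2 * logLik + 2 * k +
    if (n_obs - k - 1 > 0) 2 * k * (k + 1) / (n_obs - k - 1) else Inf
  estimates <- do.call(rbind, lapply(per_g, `[[`, "rows"))
  rownames(estimates) <- NULL

  pars <- lapply(per_g, function(p)
    p[c("I", "S", "T", "sigma", "S_range", "S_range_se")])
  fitted_curve <- function(genotype, P) {
    p <- pars[[genotype]]
    if (is.null(p)) stop("unknown genotype: ", genotype, call. = FALSE)
    if (p$S == 0) rep(p$I, length(P)) else p$I + p$S * pmax(0, p$T - P)
  }

  structure(list(
    variant = variant, estimates = estimates, params = pars,
    logLik = logLik, n_obs = n_obs, k = k, BIC = BIC, AICc = AICc,
    information_criterion = if (criterion == "BIC") BIC else AICc,
    criterion = criterion, converged = TRUE, warnings = warnings,
    tested_range = range(records$photoperiod_h),
    fitted_curve = fitted_curve
  ), class = "photoperiod_fit")
}

#' @export
print.photoperiod_fit <- function(x, ...) {
  cat(sprintf("Photoperiod response fit (variant: %s)\n", x$variant$name))
  cat(sprintf("  n = %d, k = %d, logLik = %.2f, %s = %.2f\n",
              x$n_obs, x$k, x$logLik, x$criterion, x$information_criterion))
  for (g in names(x$params)) {
    p <- x$params[[g]]
    cat(sprintf("  %-22s I = %7.1f  S = %6.2f  T = %5s  sigma = %6.2f\n",
                g, p$I, p$S,
                if (is.na(p$T)) "NA" else sprintf("%.2f", p$T), p$sigma))
  }
  if (length(x$warnings)) cat("  warnings:", length(x$warnings), "\n")
  invisible(x)
}

#' Fit and rank several model variants
#'
#' Fits each variant on the same records and ranks by the information
#' criterion (lower is better). Ties are broken by fewer parameters, then
#' by variant name; a variant whose fit errors is dropped and the error
#' summarised in the result.
#'
#' @inheritParams fit_photoperiod_model
#' @param variants List of [model_variant()] objects or names; at least
#'   one.
#' @return A list with class `"variant_comparison"`: `fits` (ranked list of
#'   fits), `table` (data.frame: variant, k, logLik, criterion value,
#'   rank), `best` (name of the top-ranked variant), `errors` (named
#'   character vector of failed variants).
#' @export
compare_variants <- function(records, variants = list("full", "flat"),
                             criterion = c("BIC", "AICc"), ...) {
  criterion <- match.arg(criterion)
  stopifnot(length(variants) >= 1)
  fits <- list(); errors <- character(0)
  for (v in variants) {
    vv <- if (is.character(v)) model_variant(v) else v
    f <- tryCatch(
      fit_photoperiod_model(records, vv, criterion = criterion, ...),
      error = function(e) e)
    if (inherits(f, "error")) {
      errors[vv$name] <- conditionMessage(f)
    } else {
      fits[[vv$name]] <- f
    }
  }
  if (!length(fits)) {
    stop("all variants failed to fit: ",
         paste(errors, collapse = "; "), call. = FALSE)
  }
  ic <- vapply(fits, `[[`, numeric(1), "information_criterion")
  kk <- vapply(fits, `[[`, numeric(1), "k")
  ord <- order(ic, kk, names(fits))
  fits <- fits[ord]
  tab <- data.frame(
    variant = names(fits),
    k = vapply(fits, `[[`, numeric(1), "k"),
    logLik = vapply(fits, `[[`, numeric(1), "logLik"),
    criterion = vapply(fits, `[[`, numeric(1), "information_criterion"),
    rank = seq_along(fits), row.names = NULL, stringsAsFactors = FALSE
  )
  names(tab)[names(tab) == "criterion"] <- criterion
  structure(list(fits = fits, table = tab, best = names(fits)[1],
                 errors = errors, criterion = criterion),
            class = "variant_comparison")
}

#' Classify each genotype's photoperiod response
#'
#' A genotype is \strong{responsive} when its sensitivity interval excludes
#' a near-zero band (default 2 degree-days/h) and its estimated threshold
#' lies above the shortest tested photoperiod; \strong{flat_saturated} when
#' the slope is indistinguishable from zero over the tested range
#' (consistent with a threshold at or below the shortest tested
#' photoperiod), judged on the straight-line slope fitted across all tested
#' photoperiods and its 95% interval lying inside the band;
#' \strong{indeterminate} otherwise. A flat_saturated call
#' cannot distinguish a photoperiod-insensitive genotype from one whose
#' threshold lies below the tested range: that would need data at shorter
#' days, and the returned note says so.
#'
#' @param fit A converged [fit_photoperiod_model()] result.
#' @param tested_range Photoperiod range `(P_min, P_max)` actually tested;
#'   defaults to the fit's observed range.
#' @param near_zero_band Slope magnitude (degree-days/h) treated as
#'   biologically indistinguishable from zero, default 2.
#' @return data.frame: genotype, classification, S and T estimates with
#'   the S interval, and a note column.
#' @export
classify_response <- function(fit, tested_range = fit$tested_range,
                              near_zero_band = 2) {
  stopifnot(inherits(fit, "photoperiod_fit"))
  if (!isTRUE(fit$converged)) {
    stop("cannot classify an unconverged fit", call. = FALSE)
  }
  p_min <- tested_range[1]
  est <- fit$estimates
  out <- lapply(names(fit$params), function(g) {
    s <- est[est$genotype == g & est$parameter == "S", ]
    t_hat <- fit$params[[g]]$T
    # range-wide straight-line slope: the quantity that decides whether a
    # response is distinguishable from flat over the tested photoperiods
    sr <- fit$params[[g]]$S_range
    sr_se <- fit$params[[g]]$S_range_se
    z <- stats::qnorm(0.975)
    range_flat <- is.finite(sr) && is.finite(sr_se) &&
      (sr + z * sr_se) < near_zero_band && (sr - z * sr_se) > -near_zero_band
    if (fit$variant$name == "flat") {
      cls <- "flat_saturated"
      note <- "sensitivity fixed at zero by the flat model variant"
    } else if (is.finite(s$lower) && s$lower > near_zero_band &&
               !is.na(t_hat) && t_hat > p_min) {
      cls <- "responsive"
      note <- sprintf("slope interval excludes %g degC d/h; threshold %.2f h",
                      near_zero_band, t_hat)
    } else if (range_flat) {
      cls <- "flat_saturated"
      note <- paste("slope indistinguishable from zero over the tested",
                    "range; cannot distinguish insensitivity from a",
                    sprintf("threshold at or below %g h without shorter-day data",
                            p_min))
    } else {
      cls <- "indeterminate"
      note <- "sensitivity interval straddles the near-zero band"
    }
    data.frame(genotype = g, classification = cls,
               S = s$estimate, S_lower = s$lower, S_upper = s$upper,
               T = t_hat, note = note, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Recommend a speed-breeding photoperiod per genotype
#'
#' Responsive genotypes gain nothing from light beyond their threshold, so
#' the recommendation is the tested photoperiod nearest the estimated
#' threshold, ties resolved upward (20 h for lines with a 20-h
#' breakpoint). Snapping to the nearest rather than the next-longer tested
#' photoperiod keeps a threshold estimated at, say, 20.2 h on the 20-h
#' setting: the implied flowering delay (sensitivity times the overshoot)
#' is a fraction of a day, while the next tested setting costs two more
#' lit hours every day.
#' Flat-saturated genotypes are already saturated at the shortest tested
#' photoperiod, which is recommended (16 h here). Indeterminate genotypes
#' fall back to a configured conservative default (22 h, the common
#' speed-breeding standard) with a warning note.
#'
#' @param classification data.frame from [classify_response()].
#' @param tested_photoperiods_h Photoperiods available in the facility,
#'   default `c(16, 18, 20, 22, 24)`.
#' @param conservative_default_h Fallback for indeterminate genotypes,
#'   default 22.
#' @return The classification data.frame with `recommended_h` and
#'   `recommendation_note` columns appended.
#' @export
recommend_photoperiod <- function(classification,
                                  tested_photoperiods_h = c(16, 18, 20, 22, 24),
                                  conservative_default_h = 22) {
  pp <- sort(tested_photoperiods_h)
  rec <- t(vapply(seq_len(nrow(classification)), function(i) {
    row <- classification[i, ]
    switch(row$classification,
      responsive = {
        nearest <- pp[order(abs(pp - row$T), -pp)][1]
        c(nearest, sprintf("tested photoperiod nearest threshold %.2f h",
                           row$T))
      },
      flat_saturated = c(pp[1],
        "saturated response: shortest tested photoperiod suffices"),
      indeterminate = c(conservative_default_h,
        "indeterminate response: conservative default photoperiod")
    )
  }, character(2)))
  classification$recommended_h <- as.numeric(rec[, 1])
  classification$recommendation_note <- rec[, 2]
  classification
}

#' Export fitted response curves on a fine photoperiod grid
#'
#' @param fit A [fit_photoperiod_model()] result.
#' @param from,to,by Photoperiod grid in hours (default 0.1-h steps over
#'   the fit's tested range).
#' @return data.frame: genotype, photoperiod_h, predicted_cd.
#' @export
fitted_curve_table <- function(fit, from = fit$tested_range[1],
                               to = fit$tested_range[2], by = 0.1) {
  grid <- seq(from, to, by = by)
  out <- lapply(names(fit$params), function(g) {
    data.frame(genotype = g, photoperiod_h = grid,
               predicted_cd = fit$fitted_curve(g, grid),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
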