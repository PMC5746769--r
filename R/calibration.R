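#' Build an immunoassay calibration curve
#'
#' Fits a four-parameter logistic (4PL) model to concentration-response
#' calibrator data and estimates the limit of detection (LOD). The 4PL is
#'
#'   f(x) = d + (a - d) / (1 + (x / c)^b)
#'
#' with `a` the zero-dose asymptote, `d` the infinite-dose asymptote, `c`
#' the midpoint concentration and `b` the slope factor. Direct and two-site
#' (sandwich) formats respond increasingly with concentration (a < d);
#' competitive formats respond decreasingly (a > d). The LOD is the
#' concentration at which the fitted curve departs from the blank mean by
#' `sd_mult` blank standard deviations, in the direction the format
#' responds.
#'
#' @param concs Calibrator concentrations (>= 5 distinct values including a
#'   zero calibrator); replicates allowed, matched to `responses` by
#'   position.
#' @param responses Responses (nm for endpoint mode, nm/s for initial-rate
#'   mode), same length as `concs`.
#' @param format `"direct"`, `"two_site"` or `"competitive"`.
#' @param mode Response mode tag: `"endpoint"` or `"initial_rate"`.
#' @param sd_mult Blank-SD multiplier in the LOD rule (default 3, the field
#'   standard; 2 is sometimes used and can be set here).
#' @return An object of class `wlrs_calibration`: fitted `params`
#'   (a, b, c, d), `lod` (with `lod_flag`: `"ok"`, `"degenerate_blank"` or
#'   `"outside_range"`), blank statistics, the calibrator table, convergence
#'   and monotonicity flags.
#' @examples
#' concs <- c(0, 0.1, 0.5, 2, 10, 50)
#' resp <- 8 + (0.2 - 8) / (1 + (concs / 2)^1.3)
#' cal <- build_calibration(concs, resp, format = "direct")
#' @export
build_calibration <- function(concs, responses,
                              format = c("direct", "two_site", "competitive"),
                              mode = c("endpoint", "initial_rate"),
                              sd_mult = 3) {
  format <- match.arg(format)
  mode <- match.arg(mode)
  check_number(sd_mult, "sd_mult", lower = 0, strict = TRUE)
  if (!is.numeric(concs) || !is.numeric(responses) ||
      length(concs) != length(responses)) {
    wlrs_invalid("`concs` and `responses` must be numeric of equal length")
  }
  if (any(concs < 0)) wlrs_invalid("concentrations must be >= 0")
  uc <- sort(unique(concs))
  if (length(uc) < 5L) wlrs_invalid("need at least 5 distinct concentrations")
  if (uc[1L] != 0) wlrs_invalid("a zero calibrator is required")

  increasing <- format %in% c("direct", "two_site")
  blank <- responses[concs == 0]
  blank_mean <- mean(blank)
  blank_sd <- if (length(blank) > 1L) sd(blank) else 0

  # mean response per level for starting values
  mlev <- vapply(uc, function(cc) mean(responses[concs == cc]), numeric(1))
  a0 <- mlev[1L]
  d0 <- mlev[length(mlev)]
  c0 <- exp(mean(log(uc[uc > 0])))
  p0 <- c(a = a0, b = 1, c = c0, d = d0)

  fpl <- function(p, x) {
    p["d"] + (p["a"] - p["d"]) / (1 + (x / p["c"])^p["b"])
  }
  res <- minpack.lm::nls.lm(
    par = p0,
    lower = c(a = -Inf, b = 1e-6, c = min(uc[uc > 0]) / 1e3, d = -Inf),
    upper = c(a = Inf, b = 50, c = max(uc) * 1e3, d = Inf),
    fn = function(p) fpl(setNames(p, names(p0)), concs) - responses,
    control = minpack.lm::nls.lm.control(ftol = 1e-12, ptol = 1e-12, maxiter = 500)
  )
  params <- setNames(coef(res), c("a", "b", "c", "d"))
  fitted_dir <- params["d"] > params["a"]
  monotone_ok <- unname(fitted_dir == increasing)

  # LOD: concentration where the fitted curve crosses blank mean -/+ sd_mult*SD
  crit <- blank_mean + (if (increasing) sd_mult else -sd_mult) * blank_sd
  lod <- NA_real_
  lod_flag <- "ok"
  if (blank_sd == 0) {
    lod <- 0
    lod_flag <- "degenerate_blank"
  } else {
    span_lo <- min(params["a"], params["d"])
    span_hi <- max(params["a"], params["d"])
    if (crit <= span_lo || crit >= span_hi) {
      lod <- max(uc)
      lod_flag <- "outside_range"
    } else {
      # invert the 4PL
      ratio <- (params["a"] - params["d"]) / (crit - params["d"]) - 1
      lod <- unname(params["c"] * ratio^(1 / params["b"]))
      if (!is.finite(lod)) {
        lod <- max(uc)
        lod_flag <- "outside_range"
      } else if (lod > max(uc)) {
        lod <- max(uc)
        lod_flag <- "outside_range"
      }
    }
  }

  structure(
    list(
      data = data.frame(concentration = concs, response = responses),
      params = params,
      format = format, mode = mode,
      lod = lod, lod_flag = lod_flag, sd_mult = sd_mult,
      blank_mean = blank_mean, blank_sd = blank_sd,
      converged = res$info %in% 1:4,
      monotone_ok = monotone_ok,
      residual_rms = sqrt(res$deviance / length(concs))
    ),
    class = "wlrs_calibration"
  )
}

#' Predict responses from a fitted calibration curve
#'
#' @param object A `wlrs_calibration`.
#' @param conc Concentrations at which to evaluate the fitted 4PL.
#' @param ... Unused.
#' @return Predicted responses.
#' @export
predict.wlrs_calibration <- function(object, conc, ...) {
  p <- object$params
  unname(p["d"] + (p["a"] - p["d"]) / (1 + (conc / p["c"])^p["b"]))
}

#' @export
print.wlrs_calibration <- function(x, ...) {
  cat(sprintf("<calibration curve> %s format, %s mode%s\n", x$format, x$mode,
              if (x$monotone_ok) "" else " [direction violated]"))
  cat(sprintf("  4PL: a = %.4g, b = %.4g, c = %.4g, d = %.4g (residual RMS %.3g)\n",
              x$params["a"], x$params["b"], x$params["c"], x$params["d"],
              x$residual_rms))
  cat(sprintf("  LOD (blank + %g SD rule): %.4g [%s]\n", x$sd_mult, x$lod, x$lod_flag))
  invisible(x)
}

#' Chip regeneration statistics
#'
#' Reusability metrics for a regenerated chip: the coefficient of variation
#' across assay/regeneration cycles and the per-cycle percent deviation from
#' the first (fresh-surface) cycle. A chip is conventionally considered
#' stable when every cycle stays within +/- 5 percent of the fresh-surface
#' signal.
#'
#' @param cycle_responses Numeric vector of per-cycle responses (>= 2
#'   cycles, all > 0).
#' @param tolerance_pct Stability band in percent (default 5).
#' @return A list: `cv_pct` (SD/mean x 100), `deviation_pct` (per cycle,
#'   relative to the first cycle), `max_deviation_pct`, `within_tolerance`.
#' @examples
#' regeneration_stats(c(100, 110)) # CV about 6.73 percent
#' @export
regeneration_stats <- function(cycle_responses, tolerance_pct = 5) {
  if (!is.numeric(cycle_responses) || length(cycle_responses) < 2L) {
    wlrs_invalid("need at least 2 cycles")
  }
  if (any(!is.finite(cycle_responses)) || any(cycle_responses <= 0)) {
    wlrs_invalid("cycle responses must be finite and > 0")
  }
  check_number(tolerance_pct, "tolerance_pct", lower = 0, strict = TRUE)
  cv <- sd(cycle_responses) / mean(cycle_responses) * 100
  dev <- (cycle_responses - cycle_responses[1L]) / cycle_responses[1L] * 100
  list(
    cv_pct = cv,
    deviation_pct = dev,
    max_deviation_pct = max(abs(dev)),
    within_tolerance = max(abs(dev)) <= tolerance_pct
  )
}
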