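#' Normalize a raw spectrum to absolute reflectance
#'
#' Converts a raw detector spectrum S(lambda) to absolute reflectance using a
#' reference spectrum REF(lambda) acquired from a plain Si chip and a dark
#' spectrum D(lambda) acquired with the source off:
#' R(lambda) = (S - D) / (REF - D), pointwise. Referencing removes the source
#' spectral envelope and the detector offset, which is what makes fitting the
#' result with the interference model meaningful.
#'
#' @param signal Raw-kind [spectrum()] S(lambda).
#' @param reference Raw or reference-kind spectrum REF(lambda) from plain Si.
#' @param dark Raw or dark-kind spectrum D(lambda), source off.
#' @return A reflectance-kind [spectrum()] on the shared grid.
#' @examples
#' grid <- wavelength_grid(points = 64)
#' ref <- spectrum(grid, rep(1000, 64), "reference")
#' drk <- spectrum(grid, rep(50, 64), "dark")
#' sig <- spectrum(grid, 50 + 0.36 * 950, "raw")
#' normalize_reflectance(sig, ref, drk) # flat 0.36
#' @export
normalize_reflectance <- function(signal, reference, dark) {
  for (sp in list(signal, reference, dark)) {
    if (!inherits(sp, "wlrs_spectrum")) {
      wlrs_invalid("all inputs must be wlrs_spectrum objects")
    }
  }
  if (!isTRUE(all.equal(signal$wavelength_nm, reference$wavelength_nm)) ||
      !isTRUE(all.equal(signal$wavelength_nm, dark$wavelength_nm))) {
    wlrs_invalid("signal, reference and dark must share an identical wavelength grid")
  }
  denom <- reference$value - dark$value
  bad <- which(denom <= 0)
  if (length(bad) > 0L) {
    wlrs_error(
      sprintf(
        "reference - dark is not positive at %d wavelength(s), first at %.6g nm",
        length(bad), signal$wavelength_nm[bad[1L]]
      ),
      "wlrs_degenerate_reference"
    )
  }
  spectrum(signal$wavelength_nm, (signal$value - dark$value) / denom,
           kind = "reflectance")
}

#' Locate interference extrema with sub-grid resolution
#'
#' Finds local minima and maxima of a spectrum within a wavelength range.
#' Candidate extrema are grid points whose value is a strict local extremum;
#' each is refined to sub-grid resolution by the vertex of the quadratic
#' through the extremum and its two neighbours. Shallow wiggles are rejected
#' by a prominence filter: an extremum must rise/fall from its bracketing
#' opposite levels by at least `prominence` times the peak-to-peak amplitude
#' of the spectrum in the range.
#'
#' @param spec A [spectrum()] (normally reflectance-kind).
#' @param range Length-2 numeric, (lo, hi) wavelength window in nm.
#' @param prominence Fraction of the in-range peak-to-peak amplitude an
#'   extremum must clear (default 0.02).
#' @return Data frame with columns `wavelength_nm` (interpolated position),
#'   `value` (interpolated extremal value) and `type` (`"min"` or `"max"`),
#'   sorted by wavelength. Zero rows if the spectrum is monotone in range.
#' @export
locate_extrema <- function(spec, range = NULL, prominence = 0.02) {
  if (!inherits(spec, "wlrs_spectrum")) wlrs_invalid("`spec` must be a wlrs_spectrum")
  if (is.null(range)) range <- range(spec$wavelength_nm)
  if (length(range) != 2L || !is.numeric(range) || range[1L] >= range[2L]) {
    wlrs_invalid("`range` must be (lo, hi) with lo < hi")
  }
  check_number(prominence, "prominence", lower = 0)
  sel <- spec$wavelength_nm >= range[1L] & spec$wavelength_nm <= range[2L]
  x <- spec$wavelength_nm[sel]
  y <- spec$value[sel]
  if (length(x) < 3L) wlrs_invalid("fewer than 3 grid points in range")

  out <- data.frame(wavelength_nm = numeric(0), value = numeric(0),
                    type = character(0), stringsAsFactors = FALSE)
  d <- diff(y)
  # strict local extrema at interior points; plateaus are skipped
  is_max <- which(head(d, -1L) > 0 & tail(d, -1L) < 0) + 1L
  is_min <- which(head(d, -1L) < 0 & tail(d, -1L) > 0) + 1L
  idx <- sort(c(is_max, is_min))
  if (length(idx) == 0L) return(out)

  amp <- diff(range(y))
  if (amp == 0) return(out)
  # prominence against bracketing levels: for each extremum the reference
  # levels are the most opposed values between it and the adjacent extremum
  # (or the window edge)
  brackets <- c(1L, idx, length(y))
  keep <- logical(length(idx))
  prom <- numeric(length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    lo <- brackets[k]        # previous extremum or window start
    hi <- brackets[k + 2L]   # next extremum or window end
    if (i %in% is_max) {
      ref_level <- max(min(y[lo:i]), min(y[i:hi]))
      prom[k] <- y[i] - ref_level
    } else {
      ref_level <- min(max(y[lo:i]), max(y[i:hi]))
      prom[k] <- ref_level - y[i]
    }
    keep[k] <- prom[k] >= prominence * amp
  }
  idx <- idx[keep]
  if (length(idx) == 0L) return(out)

  refined <- vapply(idx, function(i) {
    quad_vertex(x[(i - 1L):(i + 1L)], y[(i - 1L):(i + 1L)])
  }, numeric(2))
  data.frame(
    wavelength_nm = refined[1L, ],
    value = refined[2L, ],
    type = ifelse(idx %in% is_max, "max", "min"),
    stringsAsFactors = FALSE
  )
}

# vertex (x*, y*) of the parabola through three points; falls back to the
# middle point when the three are collinear
quad_vertex <- function(x, y) {
  X <- cbind(1, x - x[2L], (x - x[2L])^2)
  ab <- solve(X, y)
  if (ab[3L] == 0) return(c(x[2L], y[2L]))
  xs <- -ab[2L] / (2 * ab[3L])
  c(x[2L] + xs, ab[1L] - ab[2L]^2 / (4 * ab[3L]))
}

#' Count interference fringes
#'
#' Number of interference minima of a reflectance spectrum within a
#' wavelength range, after the prominence filter of [locate_extrema()]. One
#' fringe is operationalized as one reflectance minimum, the feature the
#' real-time analysis tracks.
#'
#' @inheritParams locate_extrema
#' @return Integer fringe count.
#' @examples
#' chip <- layer_stack(list(optical_layer("SiO2", 1.46, 1000)))
#' count_fringes(simulate_spectrum(chip, wavelength_grid())) # 2
#' @export
count_fringes <- function(spec, range = NULL, prominence = 0.02) {
  ext <- locate_extrema(spec, range = range, prominence = prominence)
  sum(ext$type == "min")
}

#' Timestamped spectrum series
#'
#' Container for a real-time acquisition: one spectrum per time point on a
#' shared grid.
#'
#' @param times Numeric vector of acquisition times in seconds, increasing.
#' @param spectra List of [spectrum()] objects, one per time.
#' @return An object of class `wlrs_series`.
#' @export
spectrum_series <- function(times, spectra) {
  if (!is.numeric(times) || length(times) != length(spectra)) {
    wlrs_invalid("`times` must be numeric and match `spectra` in length")
  }
  if (length(times) > 1L && any(diff(times) <= 0)) {
    wlrs_invalid("`times` must be strictly increasing")
  }
  if (!all(vapply(spectra, inherits, logical(1), "wlrs_spectrum"))) {
    wlrs_invalid("`spectra` must be a list of wlrs_spectrum objects")
  }
  structure(list(times = as.numeric(times), spectra = spectra),
            class = "wlrs_series")
}

#' @export
print.wlrs_series <- function(x, ...) {
  cat(sprintf("<spectrum series> %d frames, t = %.6g-%.6g s\n",
              length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

#' Track the main interference extremum through a spectrum series
#'
#' Follows the wavelength of the main interference extremum (lambda_max)
#' frame by frame. The search window is re-centered on the previous frame's
#' lambda_max at every step, so the tracked extremum may drift across the
#' spectrum without escaping the window; restricting the analysis to this
#' short spectral region also suppresses the effect of slow source-envelope
#' drifts. Each frame must contain exactly one sufficiently prominent
#' extremum of the tracked type inside the window.
#'
#' @param series A [spectrum_series()] of reflectance spectra.
#' @param window Length-2 numeric (lo, hi) in nm: the initial search window.
#'   The half-width is retained while the center follows the peak. Default
#'   half-width if a single center value is given: 40 nm.
#' @param type `"min"` (default; the tracked feature of SiO2-on-Si chips) or
#'   `"max"`.
#' @param prominence Passed to [locate_extrema()].
#' @return Data frame of class `wlrs_peak_track` with columns `time_s` and
#'   `lambda_max_nm`; the final window is stored in the `window` attribute.
#' @export
track_peak <- function(series, window, type = c("min", "max"),
                       prominence = 0.02) {
  if (!inherits(series, "wlrs_series")) wlrs_invalid("`series` must be a wlrs_series")
  type <- match.arg(type)
  if (length(window) == 1L) window <- window + c(-40, 40)
  if (length(window) != 2L || window[1L] >= window[2L]) {
    wlrs_invalid("`window` must be (lo, hi) with lo < hi, or a single center")
  }
  half <- diff(window) / 2
  center <- mean(window)
  lam <- numeric(length(series$times))
  for (i in seq_along(series$times)) {
    win <- center + c(-half, half)
    ext <- locate_extrema(series$spectra[[i]], range = win, prominence = prominence)
    ext <- ext[ext$type == type, , drop = FALSE]
    if (nrow(ext) != 1L) {
      wlrs_error(
        sprintf("t = %.6g s: found %d '%s' extrema in window [%.6g, %.6g] nm (need exactly 1)",
                series$times[i], nrow(ext), type, win[1L], win[2L]),
        "wlrs_tracking_failure"
      )
    }
    lam[i] <- ext$wavelength_nm
    center <- lam[i]
  }
  structure(
    data.frame(time_s = series$times, lambda_max_nm = lam),
    window = center + c(-half, half),
    class = c("wlrs_peak_track", "data.frame")
  )
}

#' Peak-shift to adlayer-thickness conversion parameters
#'
#' The simplified single-peak quantification converts a shift of the tracked
#' interference extremum directly into an adlayer thickness change through
#' delta_d1 / d2 = factor * delta_lambda / lambda_ref. The default factor
#' 2.06 is the calibration constant of the protein (n 1.46) on composite
#' SiO2-photoresist (n 1.40) on Si (n 4.00) transducer; it is stored as an
#' overridable parameter, not re-derived.
#'
#' @param d2 Composite transducer-layer thickness in nm (> 0).
#' @param lambda_ref Tracked peak wavelength before binding, nm (> 0).
#' @param factor Dimensionless conversion constant (default 2.06).
#' @return An object of class `wlrs_shift_params`.
#' @export
shift_conversion_params <- function(d2, lambda_ref, factor = 2.06) {
  check_number(d2, "d2", lower = 0, strict = TRUE)
  check_number(lambda_ref, "lambda_ref", lower = 0, strict = TRUE)
  check_number(factor, "factor", lower = 0, strict = TRUE)
  structure(list(d2 = d2, lambda_ref = lambda_ref, factor = factor),
            class = "wlrs_shift_params")
}

#' Convert a peak shift into an adlayer thickness change
#'
#' delta_d1 = factor * (delta_lambda / lambda_ref) * d2. Exactly linear and
#' homogeneous in the shift.
#'
#' @param delta_lambda Peak shift(s) in nm (vectorized; sign preserved).
#' @param params A [shift_conversion_params()].
#' @return Adlayer thickness change(s) delta_d1 in nm.
#' @examples
#' p <- shift_conversion_params(d2 = 100, lambda_ref = 600)
#' shift_to_thickness(6, p) # 2.06 nm for a 1% relative shift
#' @export
shift_to_thickness <- function(delta_lambda, params) {
  if (!inherits(params, "wlrs_shift_params")) {
    wlrs_invalid("`params` must be a wlrs_shift_params")
  }
  if (!is.numeric(delta_lambda) || any(!is.finite(delta_lambda))) {
    wlrs_invalid("`delta_lambda` must be finite")
  }
  params$factor * (delta_lambda / params$lambda_ref) * params$d2
}
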