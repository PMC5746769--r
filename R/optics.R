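#' Optical layer
#'
#' A single transparent film in a layer stack: a name, a refractive index and
#' a physical thickness in nanometers. The index may instead be given as a
#' dispersion function of wavelength (nm) returning the index, for materials
#' where a constant is too crude; by default indices are dispersionless so
#' that the canonical constants (SiO2 1.46, protein 1.40, Si 4.00) reproduce
#' textbook spectra exactly.
#'
#' @param name Text label, e.g. `"SiO2"` or `"adlayer"`.
#' @param n Refractive index, a positive dimensionless number. Ignored at
#'   evaluation time if `dispersion` is supplied.
#' @param d Thickness in nm, finite and >= 0.
#' @param dispersion Optional function `function(wavelength_nm)` returning the
#'   refractive index at each wavelength.
#' @return An object of class `wlrs_layer`.
#' @examples
#' optical_layer("SiO2", n = 1.46, d = 1000)
#' @export
optical_layer <- function(name, n, d, dispersion = NULL) {
  if (!is.character(name) || length(name) != 1L) {
    wlrs_invalid("`name` must be a single string")
  }
  check_number(n, "n", lower = 0, strict = TRUE)
  check_number(d, "d", lower = 0)
  if (!is.null(dispersion) && !is.function(dispersion)) {
    wlrs_invalid("`dispersion` must be NULL or a function of wavelength")
  }
  structure(
    list(name = name, n = n, d = d, dispersion = dispersion),
    class = "wlrs_layer"
  )
}

#' @export
print.wlrs_layer <- function(x, ...) {
  disp <- if (is.null(x$dispersion)) "" else " (dispersive)"
  cat(sprintf("<layer> %s: n = %g%s, d = %g nm\n", x$name, x$n, disp, x$d))
  invisible(x)
}

# index of a layer at given wavelength(s)
layer_index <- function(layer, wavelength) {
  if (is.null(layer$dispersion)) {
    rep_len(layer$n, length(wavelength))
  } else {
    n <- layer$dispersion(wavelength)
    if (any(!is.finite(n) | n <= 0)) {
      wlrs_invalid(sprintf("dispersion of layer '%s' returned a non-positive index", layer$name))
    }
    n
  }
}

#' Layer stack
#'
#' An ordered optical description of a sensor chip: the ambient medium on top
#' (air 1.0 or aqueous ~1.33), the films from top to bottom, and the
#' semi-infinite substrate (Si, treated as opaque so no backside reflection).
#' The medium numbering convention is fixed: ambient is medium 0, films are
#' 1..k, the substrate is k+1, and interface i separates media i-1 and i.
#'
#' @param layers List of [optical_layer()] objects, top film first. May be
#'   empty for a bare substrate.
#' @param ambient Refractive index of the ambient medium (default 1.0, air).
#' @param substrate Refractive index of the substrate (default 4.0, Si in the
#'   visible treated as a real constant).
#' @return An object of class `wlrs_stack`.
#' @examples
#' # the canonical WLRS chip: 1000 nm thermal oxide on Si, probed in air
#' chip <- layer_stack(list(optical_layer("SiO2", 1.46, 1000)))
#' @export
layer_stack <- function(layers = list(), ambient = 1.0, substrate = 4.0) {
  check_number(ambient, "ambient", lower = 0, strict = TRUE)
  check_number(substrate, "substrate", lower = 0, strict = TRUE)
  if (inherits(layers, "wlrs_layer")) layers <- list(layers)
  if (!is.list(layers) || !all(vapply(layers, inherits, logical(1), "wlrs_layer"))) {
    wlrs_invalid("`layers` must be a list of optical_layer objects")
  }
  structure(
    list(ambient = ambient, layers = layers, substrate = substrate),
    class = "wlrs_stack"
  )
}

#' @export
print.wlrs_stack <- function(x, ...) {
  cat(sprintf("<layer stack> ambient n = %g\n", x$ambient))
  for (ly in x$layers) cat("  ", format_layer(ly), "\n", sep = "")
  cat(sprintf("  substrate n = %g (semi-infinite)\n", x$substrate))
  invisible(x)
}

format_layer <- function(ly) sprintf("%s: n = %g, d = %g nm", ly$name, ly$n, ly$d)

#' Modify one layer thickness in a stack
#'
#' Convenience used throughout fitting and simulation: returns a copy of the
#' stack with the named layer's thickness replaced.
#'
#' @param stack A [layer_stack()].
#' @param layer Layer name (must match exactly one layer).
#' @param d New thickness in nm, >= 0.
#' @return The modified stack.
#' @export
set_thickness <- function(stack, layer, d) {
  idx <- stack_layer_index(stack, layer)
  check_number(d, "d", lower = 0)
  stack$layers[[idx]]$d <- d
  stack
}

stack_layer_index <- function(stack, layer) {
  nms <- vapply(stack$layers, `[[`, character(1), "name")
  idx <- which(nms == layer)
  if (length(idx) != 1L) {
    wlrs_invalid(sprintf("layer '%s' must name exactly one layer (found %d)", layer, length(idx)))
  }
  idx
}

#' Wavelength grid
#'
#' A strictly increasing vector of wavelengths in nm. The default 450-800 nm
#' span is the working range of the visible spectrometer used with Si-based
#' interference chips.
#'
#' @param from,to Range endpoints in nm, both > 0.
#' @param points Number of grid points (>= 2).
#' @return Numeric vector of wavelengths in nm.
#' @examples
#' grid <- wavelength_grid() # 450-800 nm, 512 points
#' @export
wavelength_grid <- function(from = 450, to = 800, points = 512) {
  check_number(from, "from", lower = 0, strict = TRUE)
  check_number(to, "to", lower = from, strict = TRUE)
  check_number(points, "points", lower = 2)
  seq(from, to, length.out = as.integer(points))
}

check_grid <- function(wavelength) {
  if (!is.numeric(wavelength) || length(wavelength) < 1L ||
      any(!is.finite(wavelength)) || any(wavelength <= 0)) {
    wlrs_invalid("wavelengths must be finite and > 0")
  }
  if (length(wavelength) > 1L && any(diff(wavelength) <= 0)) {
    wlrs_invalid("wavelengths must be strictly increasing")
  }
  invisible(wavelength)
}

#' Spectrum container
#'
#' A spectrum is a data frame with columns `wavelength_nm` and `value` and a
#' `kind` attribute tagging its meaning: `"raw"` (detector counts, arbitrary
#' units), `"reference"` (raw spectrum from a plain Si chip), `"dark"` (raw
#' spectrum with the source off) or `"reflectance"` (dimensionless absolute
#' reflectance in [0, 1] for non-absorbing stacks).
#'
#' @param wavelength Strictly increasing wavelengths in nm.
#' @param value Intensity values, same length as `wavelength`.
#' @param kind One of `"raw"`, `"reference"`, `"dark"`, `"reflectance"`.
#' @return A data frame of class `wlrs_spectrum`.
#' @export
spectrum <- function(wavelength, value, kind = "raw") {
  check_grid(wavelength)
  kind <- match.arg(kind, c("raw", "reference", "dark", "reflectance"))
  if (!is.numeric(value) || length(value) != length(wavelength)) {
    wlrs_invalid("`value` must be numeric and match the wavelength grid length")
  }
  structure(
    data.frame(wavelength_nm = as.numeric(wavelength), value = as.numeric(value)),
    kind = kind,
    class = c("wlrs_spectrum", "data.frame")
  )
}

#' @export
print.wlrs_spectrum <- function(x, ...) {
  cat(sprintf(
    "<spectrum: %s> %d points, %.6g-%.6g nm, value range [%.6g, %.6g]\n",
    attr(x, "kind"), nrow(x), min(x$wavelength_nm), max(x$wavelength_nm),
    min(x$value), max(x$value)
  ))
  invisible(x)
}

spectrum_kind <- function(spec) attr(spec, "kind") %||% "raw"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normal-incidence Fresnel amplitude coefficient
#'
#' Amplitude reflection coefficient r = (n_i - n_j) / (n_i + n_j) for light
#' travelling from medium i into medium j at normal incidence. Antisymmetric
#' under exchange of the media; zero for index-matched media.
#'
#' @param n_i,n_j Refractive indices of the incidence and transmission media,
#'   both > 0. Vectorized.
#' @return Signed dimensionless reflection amplitude in (-1, 1).
#' @examples
#' fresnel_amplitude(1.0, 4.0) # air | Si: -0.6
#' @export
fresnel_amplitude <- function(n_i, n_j) {
  if (!is.numeric(n_i) || !is.numeric(n_j) ||
      any(!is.finite(n_i)) || any(!is.finite(n_j)) ||
      any(n_i <= 0) || any(n_j <= 0)) {
    wlrs_invalid("refractive indices must be finite and > 0")
  }
  (n_i - n_j) / (n_i + n_j)
}

#' One-pass phase thickness of a film
#'
#' The phase accumulated by one traversal of a film at normal incidence,
#' delta = 2 pi n d / lambda (radians). The interference equations use the
#' round trip, 2 delta = 4 pi n d / lambda, inside their cosines.
#'
#' @param n Refractive index of the film (> 0). Vectorized with `wavelength`.
#' @param d Film thickness in nm (>= 0).
#' @param wavelength Wavelength in nm (> 0). Vectorized.
#' @return Phase in radians.
#' @examples
#' phase_thickness(1.46, 1000, 2920) # == pi: lambda = 2 n d
#' @export
phase_thickness <- function(n, d, wavelength) {
  if (any(!is.finite(wavelength)) || any(wavelength <= 0)) {
    wlrs_invalid("`wavelength` must be finite and > 0")
  }
  if (any(!is.finite(n)) || any(n <= 0)) wlrs_invalid("`n` must be finite and > 0")
  if (any(!is.finite(d)) || any(d < 0)) wlrs_invalid("`d` must be finite and >= 0")
  2 * pi * n * d / wavelength
}

#' Effective reflection coefficient of a multilayer stack
#'
#' Backward (substrate-up) recursion over the stack combining interface
#' Fresnel amplitudes and layer round-trip phase factors into a single
#' effective complex reflection coefficient: starting from the bare Fresnel
#' coefficient at the deepest interface, each film folds its round-trip phase
#' exp(-2i delta) into
#' r_eff <- (r_top + r_eff exp(-2i delta)) / (1 + r_top r_eff exp(-2i delta)).
#' The squared modulus of the result is the stack reflectance. Complex
#' arithmetic is used throughout; the substrate is semi-infinite.
#'
#' @param stack A [layer_stack()].
#' @param wavelength Wavelengths in nm (vectorized, each > 0).
#' @return Complex vector of effective reflection coefficients, one per
#'   wavelength.
#' @examples
#' bare_si <- layer_stack()
#' Mod(effective_reflectance(bare_si, 600))^2 # 0.36
#' @export
effective_reflectance <- function(stack, wavelength) {
  if (!inherits(stack, "wlrs_stack")) wlrs_invalid("`stack` must be a wlrs_stack")
  if (length(wavelength) == 0L) wlrs_invalid("`wavelength` must be non-empty")
  if (any(!is.finite(wavelength)) || any(wavelength <= 0)) {
    wlrs_invalid("`wavelength` must be finite and > 0")
  }
  k <- length(stack$layers)
  # per-wavelength index of each medium, ambient first
  n <- matrix(0, nrow = k + 2L, ncol = length(wavelength))
  n[1L, ] <- stack$ambient
  if (k > 0L) {
    for (j in seq_len(k)) n[j + 1L, ] <- layer_index(stack$layers[[j]], wavelength)
  }
  n[k + 2L, ] <- stack$substrate

  r_eff <- as.complex(fresnel_amplitude(n[k + 1L, ], n[k + 2L, ]))
  if (k > 0L) {
    for (j in rev(seq_len(k))) {
      delta <- phase_thickness(n[j + 1L, ], stack$layers[[j]]$d, wavelength)
      phase <- exp(-2i * delta)
      r_top <- fresnel_amplitude(n[j, ], n[j + 1L, ])
      r_eff <- (r_top + r_eff * phase) / (1 + r_top * r_eff * phase)
    }
  }
  if (any(!is.finite(Re(r_eff)) | !is.finite(Im(r_eff)))) {
    wlrs_error("non-finite value in reflectance recursion", "wlrs_numeric_error")
  }
  r_eff
}

#' Two-layer reflectance, explicit closed form
#'
#' The total reflected energy E = A / B of an ambient | film 1 | film 2 |
#' substrate system at normal incidence, written out as the trigonometric
#' expansion of the squared modulus of the two-layer Airy coefficient. With
#' r01, r12, r23 the interface Fresnel amplitudes and the round-trip phases
#' 2 delta_i = 4 pi n_i d_i / lambda:
#'
#' A = r01^2 + r12^2 + r23^2 + r01^2 r12^2 r23^2
#'     + 2 r01 r12 (1 + r23^2) cos(4 pi n1 d1 / lambda)
#'     + 2 r12 r23 (1 + r01^2) cos(4 pi n2 d2 / lambda)
#'     + 2 r01 r23 cos(4 pi (n1 d1 + n2 d2) / lambda)
#'     + 2 r01 r12^2 r23 cos(4 pi (n1 d1 - n2 d2) / lambda)
#'
#' B = 1 + r01^2 r12^2 + r01^2 r23^2 + r12^2 r23^2
#'     + 2 r01 r12 (1 + r23^2) cos(4 pi n1 d1 / lambda)
#'     + 2 r12 r23 (1 + r01^2) cos(4 pi n2 d2 / lambda)
#'     + 2 r01 r23 cos(4 pi (n1 d1 + n2 d2) / lambda)
#'     + 2 r01 r12^2 r23 cos(4 pi (n1 d1 - n2 d2) / lambda)
#'
#' Algebraically identical to [effective_reflectance()] on the same stack but
#' computed by a fully independent real-trigonometric code path, which makes
#' the pair a strong mutual cross-check.
#'
#' @param n0,n1,n2,n3 Refractive indices of ambient, film 1, film 2 and
#'   substrate (all > 0).
#' @param d1,d2 Film thicknesses in nm (>= 0).
#' @param wavelength Wavelengths in nm (vectorized).
#' @return Reflectance E in [0, 1], one value per wavelength.
#' @examples
#' reflectance_two_layer(1.0, 1.46, 1.40, 4.0, 100, 1000, 600)
#' @export
reflectance_two_layer <- function(n0, n1, n2, n3, d1, d2, wavelength) {
  for (nm in c("n0", "n1", "n2", "n3")) {
    check_number(get(nm), nm, lower = 0, strict = TRUE)
  }
  check_number(d1, "d1", lower = 0)
  check_number(d2, "d2", lower = 0)
  if (any(!is.finite(wavelength)) || any(wavelength <= 0)) {
    wlrs_invalid("`wavelength` must be finite and > 0")
  }
  r01 <- fresnel_amplitude(n0, n1)
  r12 <- fresnel_amplitude(n1, n2)
  r23 <- fresnel_amplitude(n2, n3)
  p1 <- 4 * pi * n1 * d1 / wavelength       # round-trip phase, film 1
  p2 <- 4 * pi * n2 * d2 / wavelength       # round-trip phase, film 2

  cross <- 2 * r01 * r12 * (1 + r23^2) * cos(p1) +
    2 * r12 * r23 * (1 + r01^2) * cos(p2) +
    2 * r01 * r23 * cos(p1 + p2) +
    2 * r01 * r12^2 * r23 * cos(p1 - p2)

  A <- r01^2 + r12^2 + r23^2 + (r01 * r12 * r23)^2 + cross
  B <- 1 + (r01 * r12)^2 + (r01 * r23)^2 + (r12 * r23)^2 + cross
  E <- A / B
  if (any(!is.finite(E))) {
    wlrs_error("non-finite intermediate in two-layer closed form", "wlrs_numeric_error")
  }
  E
}

#' Simulate a reflectance spectrum
#'
#' Evaluates the stack reflectance |r_eff|^2 on a wavelength grid.
#' Deterministic; dispersionless indices unless layers carry dispersion
#' functions.
#'
#' @param stack A [layer_stack()].
#' @param grid Wavelength grid in nm (see [wavelength_grid()]).
#' @return A reflectance-kind [spectrum()].
#' @examples
#' chip <- layer_stack(list(optical_layer("SiO2", 1.46, 1000)))
#' sp <- simulate_spectrum(chip, wavelength_grid())
#' @export
simulate_spectrum <- function(stack, grid = wavelength_grid()) {
  check_grid(grid)
  r <- effective_reflectance(stack, grid)
  spectrum(grid, Mod(r)^2, kind = "reflectance")
}
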