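#' Sensorgram container
#'
#' Time course of the adlayer thickness (or, with `units = "nm_shift"`, of
#' the tracked peak shift) during a binding, swelling or regeneration
#' experiment.
#'
#' @param times Times in seconds, increasing, starting at or after 0.
#' @param thickness Thickness (or shift) in nm per time point, >= 0.
#' @param units `"nm"` (adlayer thickness, default) or `"nm_shift"`.
#' @return Data frame of class `wlrs_sensorgram` with columns `time_s`,
#'   `thickness_nm`.
#' @export
sensorgram <- function(times, thickness, units = c("nm", "nm_shift")) {
  units <- match.arg(units)
  if (!is.numeric(times) || !is.numeric(thickness) ||
      length(times) != length(thickness)) {
    wlrs_invalid("`times` and `thickness` must be numeric of equal length")
  }
  if (length(times) > 1L && any(diff(times) <= 0)) {
    wlrs_invalid("`times` must be strictly increasing")
  }
  structure(
    data.frame(time_s = as.numeric(times), thickness_nm = as.numeric(thickness)),
    units = units,
    class = c("wlrs_sensorgram", "data.frame")
  )
}

#' Langmuir 1:1 binding parameters
#'
#' The minimal standard kinetic model for analyte capture on an immobilized
#' receptor: association rate k_on * C, dissociation rate k_off, fractional
#' surface occupancy theta(t), and a uniform adlayer whose thickness grows
#' proportionally to theta up to `d_max` at saturation. The equilibrium
#' dissociation constant is K_D = k_off / k_on.
#'
#' @param k_on Association rate constant, 1/(M s), >= 0.
#' @param k_off Dissociation rate constant, 1/s, >= 0.
#' @param conc Analyte concentration, M, >= 0.
#' @param d_max Adlayer thickness at surface saturation, nm, > 0.
#' @return An object of class `wlrs_binding_params`.
#' @examples
#' binding_params(k_on = 1e5, k_off = 1e-3, conc = 1e-8, d_max = 5)
#' @export
binding_params <- function(k_on, k_off, conc, d_max) {
  check_number(k_on, "k_on", lower = 0)
  check_number(k_off, "k_off", lower = 0)
  check_number(conc, "conc", lower = 0)
  check_number(d_max, "d_max", lower = 0, strict = TRUE)
  structure(list(k_on = k_on, k_off = k_off, conc = conc, d_max = d_max),
            class = "wlrs_binding_params")
}

#' Simulate a Langmuir binding sensorgram
#'
#' Closed-form 1:1 Langmuir association starting from occupancy `theta0`:
#' d(t) = d_max * (theta_eq + (theta0 - theta_eq) * exp(-(k_on C + k_off) t))
#' with theta_eq = k_on C / (k_on C + k_off) = C / (C + K_D). With `conc = 0`
#' this is the dissociation phase, decaying from the current occupancy. The
#' initial slope is d'(0) = d_max * (k_on C (1 - theta0) - k_off theta0),
#' i.e. d_max * k_on * C on an empty surface.
#'
#' @param params A [binding_params()].
#' @param times Times in s, increasing, starting at 0.
#' @param theta0 Initial fractional occupancy in [0, 1] (default 0, bare
#'   surface; use the association plateau to chain a dissociation phase).
#' @return A [sensorgram()].
#' @examples
#' p <- binding_params(1e5, 1e-3, 1e-8, 5)
#' sg <- simulate_binding(p, seq(0, 600, by = 1))
#' @export
simulate_binding <- function(params, times, theta0 = 0) {
  if (!inherits(params, "wlrs_binding_params")) {
    wlrs_invalid("`params` must be a wlrs_binding_params")
  }
  if (!is.numeric(times) || length(times) < 1L || times[1L] < 0) {
    wlrs_invalid("`times` must be numeric, starting at >= 0")
  }
  check_number(theta0, "theta0", lower = 0)
  if (theta0 > 1) wlrs_invalid("`theta0` must be <= 1")
  rate <- params$k_on * params$conc + params$k_off
  theta_eq <- if (rate > 0) params$k_on * params$conc / rate else theta0
  theta <- theta_eq + (theta0 - theta_eq) * exp(-rate * times)
  sensorgram(times, params$d_max * theta)
}

#' Simulate a polymer swelling sensorgram
#'
#' First-order relaxation model for vapor sorption into a polymer film: on
#' exposure the thickness relaxes exponentially from `baseline` towards
#' baseline * (1 + equilibrium_swelling) with time constant `tau`; on purge
#' (desorption) it relaxes back symmetrically. Sorption runs on
#' `[0, t_switch]`, desorption afterwards; `t_switch = Inf` gives pure
#' sorption.
#'
#' @param equilibrium_swelling Fractional thickness increase at sorption
#'   equilibrium (>= 0; e.g. 0.05 for 5 percent swelling).
#' @param tau Relaxation time constant in s (> 0).
#' @param baseline Dry film thickness in nm (> 0).
#' @param times Times in s, increasing, starting at >= 0.
#' @param t_switch Time at which the vapor is purged (default `Inf`).
#' @return A [sensorgram()].
#' @export
simulate_swelling <- function(equilibrium_swelling, tau, baseline, times,
                              t_switch = Inf) {
  check_number(equilibrium_swelling, "equilibrium_swelling", lower = 0)
  check_number(tau, "tau", lower = 0, strict = TRUE)
  check_number(baseline, "baseline", lower = 0, strict = TRUE)
  if (!is.numeric(times) || length(times) < 1L || times[1L] < 0) {
    wlrs_invalid("`times` must be numeric, starting at >= 0")
  }
  d_eq <- baseline * (1 + equilibrium_swelling)
  d <- d_eq + (baseline - d_eq) * exp(-times / tau)
  if (is.finite(t_switch)) {
    after <- times > t_switch
    d_at_switch <- d_eq + (baseline - d_eq) * exp(-t_switch / tau)
    d[after] <- baseline + (d_at_switch - baseline) * exp(-(times[after] - t_switch) / tau)
  }
  sensorgram(times, d)
}

#' Render a sensorgram as a noisy spectrum series
#'
#' Bridges the kinetic generator to the spectral fitter: for every time
#' point, the designated adlayer of the stack is set to the sensorgram
#' thickness, the forward model produces the reflectance spectrum, and
#' per-wavelength independent multiplicative Gaussian noise of fractional
#' standard deviation `noise_sd` is applied. Bit-reproducible for a fixed
#' seed.
#'
#' @param sg A [sensorgram()].
#' @param stack Model [layer_stack()] containing the adlayer.
#' @param adlayer Name of the layer driven by the sensorgram.
#' @param grid Wavelength grid in nm.
#' @param noise_sd Fractional noise SD (default 0, noiseless).
#' @param seed Integer seed used when `noise_sd > 0`.
#' @return A [spectrum_series()].
#' @export
sensorgram_to_spectra <- function(sg, stack, adlayer, grid = wavelength_grid(),
                                  noise_sd = 0, seed = 1L) {
  if (!inherits(sg, "wlrs_sensorgram")) wlrs_invalid("`sg` must be a wlrs_sensorgram")
  stack_layer_index(stack, adlayer)
  check_grid(grid)
  check_number(noise_sd, "noise_sd", lower = 0)
  if (noise_sd > 0) set.seed(seed)
  spectra <- vector("list", nrow(sg))
  for (i in seq_len(nrow(sg))) {
    st <- set_thickness(stack, adlayer, sg$thickness_nm[i])
    sp <- simulate_spectrum(st, grid)
    if (noise_sd > 0) {
      sp$value <- sp$value * (1 + rnorm(length(grid), sd = noise_sd))
    }
    spectra[[i]] <- sp
  }
  spectrum_series(sg$time_s, spectra)
}

#' Apply a reagent signal-enhancement gain
#'
#' Two-site (sandwich) detection steps and secondary-antibody or
#' streptavidin enhancement are modeled as a multiplicative gain on the
#' adlayer response: each added reagent layer couples extra mass per
#' captured analyte molecule, scaling the optical thickness signal. The
#' default gain of 4 reflects the signal increase typically obtained from a
#' polyclonal secondary antibody step.
#'
#' @param sg A [sensorgram()] of the primary binding response.
#' @param gain Multiplicative signal gain (> 0; default 4).
#' @return The scaled [sensorgram()].
#' @export
enhance_response <- function(sg, gain = 4) {
  if (!inherits(sg, "wlrs_sensorgram")) wlrs_invalid("`sg` must be a wlrs_sensorgram")
  check_number(gain, "gain", lower = 0, strict = TRUE)
  sg$thickness_nm <- sg$thickness_nm * gain
  sg
}

#' Endpoint signal of a sensorgram
#'
#' Thickness gained between the start of the reaction and `t_end`, with
#' linear interpolation between samples. The classic fixed-time assay
#' readout (e.g. the signal after 10 min of reaction).
#'
#' @param sg A [sensorgram()].
#' @param t_end End of the reaction window in s, within the recorded range.
#' @return Thickness change in nm.
#' @export
endpoint_signal <- function(sg, t_end) {
  if (!inherits(sg, "wlrs_sensorgram")) wlrs_invalid("`sg` must be a wlrs_sensorgram")
  check_number(t_end, "t_end", lower = min(sg$time_s))
  if (t_end > max(sg$time_s)) wlrs_invalid("`t_end` is beyond the recorded time range")
  d_end <- approx(sg$time_s, sg$thickness_nm, xout = t_end)$y
  d_end - sg$thickness_nm[1L]
}

#' Initial reaction rate of a sensorgram
#'
#' Least-squares slope of thickness versus time over the first `window`
#' seconds. Quantifying from the initial rate instead of the endpoint
#' shortens the assay: at low occupancy the slope is d_max * k_on * C,
#' directly proportional to the analyte concentration when C << K_D.
#'
#' @param sg A [sensorgram()].
#' @param window Length of the initial window in s (default 60); must
#'   contain at least 3 samples.
#' @return Rate in nm/s.
#' @export
initial_rate <- function(sg, window = 60) {
  if (!inherits(sg, "wlrs_sensorgram")) wlrs_invalid("`sg` must be a wlrs_sensorgram")
  check_number(window, "window", lower = 0, strict = TRUE)
  if (window > max(sg$time_s) - sg$time_s[1L]) {
    wlrs_invalid("`window` exceeds the sensorgram duration")
  }
  sel <- sg$time_s <= sg$time_s[1L] + window
  if (sum(sel) < 3L) wlrs_invalid("need at least 3 samples in the initial window")
  unname(coef(lm(thickness_nm ~ time_s, data = sg[sel, ]))[2L])
}
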