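# Independent characteristic-matrix (transfer-matrix) computation of
# normal-incidence multilayer reflectance. Deliberately a different
# algorithm from both code paths in the package: it propagates the 2x2
# characteristic matrix of each film and converts to the reflection
# amplitude only at the end.
tmm_reflectance <- function(ns, ds, lambda) {
  vapply(lambda, function(lam) {
    M <- diag(2)
    for (j in seq_along(ds)) {
      n <- ns[j + 1L]
      delta <- 2 * pi * n * ds[j] / lam
      Mj <- matrix(c(cos(delta), 1i * n * sin(delta),
                     1i * sin(delta) / n, cos(delta)), 2L, 2L)
      M <- M %*% Mj
    }
    n0 <- ns[1L]
    ns_sub <- ns[length(ns)]
    r <- (n0 * M[1, 1] + n0 * ns_sub * M[1, 2] - M[2, 1] - ns_sub * M[2, 2]) /
      (n0 * M[1, 1] + n0 * ns_sub * M[1, 2] + M[2, 1] + ns_sub * M[2, 2])
    Mod(r)^2
  }, numeric(1))
}

# single-film Airy reflectance, closed form (second independent route for
# one-layer stacks)
airy_reflectance <- function(n0, n1, n2, d, lambda) {
  r01 <- (n0 - n1) / (n0 + n1)
  r12 <- (n1 - n2) / (n1 + n2)
  beta <- 2 * pi * n1 * d / lambda
  r <- (r01 + r12 * exp(-2i * beta)) / (1 + r01 * r12 * exp(-2i * beta))
  Mod(r)^2
}

# random physically plausible two-layer stack on a high-index substrate
random_two_layer <- function() {
  list(
    n0 = runif(1, 1.0, 1.5),
    n1 = runif(1, 1.2, 2.5),
    n2 = runif(1, 1.2, 2.5),
    n3 = runif(1, 2.5, 4.5),
    d1 = runif(1, 5, 1500),
    d2 = runif(1, 5, 1500)
  )
}

# the canonical chip: (optional) protein adlayer on 1000 nm thermal SiO2 on Si
canonical_chip <- function(adlayer_nm = NULL, oxide_nm = 1000) {
  layers <- list()
  if (!is.null(adlayer_nm)) {
    layers <- c(layers, list(optical_layer("adlayer", 1.46, adlayer_nm)))
  }
  layers <- c(layers, list(optical_layer("SiO2", 1.46, oxide_nm)))
  layer_stack(layers)
}

# oracle lambda_max of the tracked interference minimum: extremum location
# on a very dense grid, independent of the tracking path
oracle_lambda_min <- function(stack, window, points = 8192) {
  grid <- seq(window[1L], window[2L], length.out = points)
  sp <- simulate_spectrum(stack, grid)
  ext <- locate_extrema(sp)
  ext <- ext[ext$type == "min", , drop = FALSE]
  stopifnot(nrow(ext) == 1L)
  ext$wavelength_nm
}
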