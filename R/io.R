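#' Read a spectrum from a two-column delimited text file
#'
#' Expects a header line `wavelength_nm,value` followed by one numeric row
#' per grid point; comment lines starting with `#` (provenance headers
#' written by the package) are ignored. Wavelengths must be strictly
#' increasing. Round-trips with [write_spectrum()] at full precision.
#'
#' @param path File path.
#' @param kind Spectrum kind tag to attach (default `"raw"`; files written
#'   by the package record their kind in a comment and it is recovered
#'   automatically).
#' @return A [spectrum()].
#' @export
read_spectrum <- function(path, kind = NULL) {
  if (!file.exists(path)) {
    wlrs_error(sprintf("file not found: %s", path), "wlrs_missing_file")
  }
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  if (is.null(kind)) {
    km <- grep("^# kind = ", meta, value = TRUE)
    kind <- if (length(km) > 0L) sub("^# kind = ", "", km[1L]) else "raw"
  }
  body_idx <- grep("^#", lines, invert = TRUE)
  body <- lines[body_idx]
  if (length(body) < 2L || trimws(body[1L]) != "wavelength_nm,value") {
    wlrs_error(sprintf("%s: expected header 'wavelength_nm,value'", path),
               "wlrs_format_error")
  }
  rows <- strsplit(body[-1L], ",", fixed = TRUE)
  n <- length(rows)
  wl <- val <- numeric(n)
  for (i in seq_len(n)) {
    r <- suppressWarnings(as.numeric(rows[[i]]))
    if (length(r) != 2L || any(!is.finite(r))) {
      wlrs_error(
        sprintf("%s: malformed row at line %d", path, body_idx[i + 1L]),
        "wlrs_format_error"
      )
    }
    wl[i] <- r[1L]; val[i] <- r[2L]
  }
  if (n > 1L && any(diff(wl) <= 0)) {
    wlrs_error(sprintf("%s: wavelengths must be strictly increasing", path),
               "wlrs_format_error")
  }
  spectrum(wl, val, kind = kind)
}

#' Write a spectrum to a two-column delimited text file
#'
#' @param spec A [spectrum()].
#' @param path Output path.
#' @param header Optional named character/numeric vector written as
#'   `# name = value` provenance comment lines (a `seed`, a config hash, a
#'   timestamp). The spectrum kind is always recorded.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spec, path, header = NULL) {
  if (!inherits(spec, "wlrs_spectrum")) wlrs_invalid("`spec` must be a wlrs_spectrum")
  lines <- c(
    sprintf("# kind = %s", spectrum_kind(spec)),
    if (!is.null(header)) sprintf("# %s = %s", names(header), as.character(header)),
    "wavelength_nm,value",
    sprintf("%.17g,%.17g", spec$wavelength_nm, spec$value)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write / read a sensorgram as delimited text
#'
#' Format: optional `#` provenance comments, header
#' `time_s,thickness_nm[,converged]`, one row per time point.
#'
#' @param sg A [sensorgram()] (possibly with a `converged` column).
#' @param path File path.
#' @param header Optional named vector of provenance comments.
#' @return `path` (write) or a [sensorgram()] (read).
#' @export
write_sensorgram <- function(sg, path, header = NULL) {
  if (!inherits(sg, "wlrs_sensorgram")) wlrs_invalid("`sg` must be a wlrs_sensorgram")
  has_conv <- "converged" %in% names(sg)
  hdr <- if (has_conv) "time_s,thickness_nm,converged" else "time_s,thickness_nm"
  rows <- if (has_conv) {
    sprintf("%.17g,%.17g,%d", sg$time_s, sg$thickness_nm, as.integer(sg$converged))
  } else {
    sprintf("%.17g,%.17g", sg$time_s, sg$thickness_nm)
  }
  writeLines(c(if (!is.null(header)) sprintf("# %s = %s", names(header), as.character(header)),
               hdr, rows), path)
  invisible(path)
}

#' @rdname write_sensorgram
#' @export
read_sensorgram <- function(path) {
  if (!file.exists(path)) {
    wlrs_error(sprintf("file not found: %s", path), "wlrs_missing_file")
  }
  df <- read.csv(path, comment.char = "#")
  if (!all(c("time_s", "thickness_nm") %in% names(df))) {
    wlrs_error(sprintf("%s: expected columns time_s,thickness_nm", path),
               "wlrs_format_error")
  }
  sg <- sensorgram(df$time_s, df$thickness_nm)
  if ("converged" %in% names(df)) sg$converged <- as.logical(df$converged)
  sg
}

#' Read a calibrator table
#'
#' Delimited text with header `concentration,response` (comment lines with
#' `#` allowed), one calibrator measurement per row.
#'
#' @param path File path.
#' @return Data frame with columns `concentration` and `response`.
#' @export
read_calibrators <- function(path) {
  if (!file.exists(path)) {
    wlrs_error(sprintf("file not found: %s", path), "wlrs_missing_file")
  }
  df <- read.csv(path, comment.char = "#")
  if (!all(c("concentration", "response") %in% names(df))) {
    wlrs_error(sprintf("%s: expected columns concentration,response", path),
               "wlrs_format_error")
  }
  df[c("concentration", "response")]
}

# ---- run configuration ------------------------------------------------------

config_known_keys <- function() {
  c("stack.ambient", "stack.substrate",
    "grid.from", "grid.to", "grid.points",
    "fit.free", "fit.free_index", "fit.window",
    "kinetics.k_on", "kinetics.k_off", "kinetics.conc", "kinetics.d_max",
    "kinetics.duration", "kinetics.dt",
    "noise.sd", "seed",
    "scan.band_width", "scan.band_pitch", "scan.n_bands", "scan.spot_fwhm",
    "scan.step",
    "calibrate.format", "calibrate.mode", "calibrate.sd_mult",
    "resolve.replicates")
}

#' Read a run configuration file
#'
#' Flat key-value dialect with dotted section names, one `key = value` pair
#' per line; `#` starts a comment. Layers are declared as
#' `layer.<i>.name/n/d` with consecutive indices from 1 (top film first).
#' Every other key must be one of the known configuration keys; unknown keys
#' are rejected with a named error so that typos never silently change a
#' run.
#'
#' @param path File path.
#' @return A named list of configuration values (numbers parsed, lists such
#'   as `fit.window` split on commas), with layers gathered under `layers`.
#' @examples
#' cfg <- tempfile(fileext = ".cfg")
#' writeLines(c(
#'   "stack.ambient = 1.0", "stack.substrate = 4.0",
#'   "layer.1.name = SiO2", "layer.1.n = 1.46", "layer.1.d = 1000",
#'   "grid.from = 450", "grid.to = 800", "grid.points = 512"
#' ), cfg)
#' conf <- read_run_config(cfg)
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    wlrs_error(sprintf("file not found: %s", path), "wlrs_missing_file")
  }
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  conf <- list()
  layer_raw <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "=", fixed = TRUE)[[1L]]
    if (length(parts) != 2L) {
      wlrs_error(sprintf("%s: malformed line '%s'", path, lines[i]),
                 "wlrs_config_error")
    }
    key <- trimws(parts[1L]); val <- trimws(parts[2L])
    if (grepl("^layer\\.[0-9]+\\.(name|n|d)$", key)) {
      layer_raw[[key]] <- val
    } else if (key %in% config_known_keys()) {
      conf[[key]] <- val
    } else {
      wlrs_error(sprintf("%s: unknown configuration key '%s'", path, key),
                 "wlrs_config_error")
    }
  }
  # numeric coercion for everything except explicit text keys
  text_keys <- c("fit.free", "fit.free_index", "calibrate.format", "calibrate.mode")
  for (key in names(conf)) {
    if (key %in% text_keys) next
    if (key == "fit.window") {
      conf[[key]] <- as.numeric(strsplit(conf[[key]], ",")[[1L]])
      next
    }
    v <- suppressWarnings(as.numeric(conf[[key]]))
    if (is.na(v)) {
      wlrs_error(sprintf("%s: value of '%s' is not numeric", path, key),
                 "wlrs_config_error")
    }
    conf[[key]] <- v
  }
  if ("fit.free" %in% names(conf)) {
    conf[["fit.free"]] <- trimws(strsplit(conf[["fit.free"]], ",")[[1L]])
  }
  # gather layers by index
  if (length(layer_raw) > 0L) {
    idx <- sort(unique(as.integer(sub("^layer\\.([0-9]+)\\..*$", "\\1", names(layer_raw)))))
    if (!identical(idx, seq_along(idx))) {
      wlrs_error(sprintf("%s: layer indices must be consecutive from 1", path),
                 "wlrs_config_error")
    }
    layers <- vector("list", length(idx))
    for (j in idx) {
      nm <- layer_raw[[sprintf("layer.%d.name", j)]]
      n <- suppressWarnings(as.numeric(layer_raw[[sprintf("layer.%d.n", j)]]))
      d <- suppressWarnings(as.numeric(layer_raw[[sprintf("layer.%d.d", j)]]))
      if (is.null(nm) || is.na(n) || is.na(d)) {
        wlrs_error(sprintf("%s: layer %d needs name, n and d", path, j),
                   "wlrs_config_error")
      }
      layers[[j]] <- optical_layer(nm, n, d)
    }
    conf$layers <- layers
  }
  conf
}

#' Build package objects from a run configuration
#'
#' `config_stack()` assembles the [layer_stack()], `config_grid()` the
#' wavelength grid, and `config_problem()` the [fit_problem()] declared in a
#' configuration read by [read_run_config()].
#'
#' @param conf A configuration list from [read_run_config()].
#' @return The corresponding package object.
#' @export
config_stack <- function(conf) {
  layer_stack(
    layers = conf$layers %||% list(),
    ambient = conf[["stack.ambient"]] %||% 1.0,
    substrate = conf[["stack.substrate"]] %||% 4.0
  )
}

#' @rdname config_stack
#' @export
config_grid <- function(conf) {
  wavelength_grid(
    from = conf[["grid.from"]] %||% 450,
    to = conf[["grid.to"]] %||% 800,
    points = conf[["grid.points"]] %||% 512
  )
}

#' @rdname config_stack
#' @export
config_problem <- function(conf) {
  free <- conf[["fit.free"]]
  if (is.null(free)) {
    wlrs_error("configuration declares no free parameters (fit.free)",
               "wlrs_config_error")
  }
  fit_problem(
    config_stack(conf), free = free,
    free_index = conf[["fit.free_index"]],
    window = conf[["fit.window"]],
    grid = config_grid(conf)
  )
}
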