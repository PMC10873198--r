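#' Analysis configuration
#'
#' Bundles every tunable threshold and grid used across the package so that a
#' whole analysis is reproducible from a single object.  Defaults follow the
#' published three-channel ratiometric FRET protocol: emission spectra on a
#' 450--600 nm grid at 0.5 nm, segmentation of raw 16-bit counts between
#' 1,500 and 40,000, particles kept for areas of 65--845 square microns and
#' circularity 0.1--1.0, cells excluded above 10,000 donor counts, above a
#' 2,000-count change in direct acceptor emission, or outside a corrected
#' donor/acceptor ratio of 0--6.
#'
#' @param wavelength_grid_start,wavelength_grid_end Emission grid limits (nm).
#' @param wavelength_step Grid spacing (nm).
#' @param pixel_size Image pixel size in microns per pixel.
#' @param seed Default seed for stochastic operations that are not given one.
#' @param guinier_qrg_limit Maximum allowed q*Rg in a Guinier fit.
#' @param forster_r0 Forster distance in Angstrom (mTurquoise2--mNeonGreen).
#' @param seg_low,seg_high Segmentation intensity window (raw counts).
#' @param area_range Particle area window in square microns, ordered pair.
#' @param circularity_range Particle circularity window, ordered pair.
#' @param intensity_cap Donor-channel mean above which a cell is flagged.
#' @param direct_change_cap Allowed absolute change in direct acceptor counts.
#' @param ratio_cap Upper bound on the corrected donor/acceptor ratio.
#' @param background_offset Camera offset in counts (subtracted only when
#'   `subtract_background` is `TRUE`).
#' @param subtract_background Subtract the median of non-cell pixels per
#'   channel and frame before averaging regions.  Off by default so the raw
#'   count thresholds above apply directly.
#' @param ratio_filter_timepoint Apply the donor/acceptor ratio filter to the
#'   `"before"` timepoint only (default) or to `"both"`.
#' @param intensity_cap_channel Channel tested against `intensity_cap`.
#' @return An object of class `idrfret_config` (a validated list).
#' @examples
#' cfg <- fret_config()
#' cfg$forster_r0
#' @export
fret_config <- function(wavelength_grid_start = 450,
                        wavelength_grid_end = 600,
                        wavelength_step = 0.5,
                        pixel_size = 0.65,
                        seed = 1L,
                        guinier_qrg_limit = 1.0,
                        forster_r0 = 62,
                        seg_low = 1500,
                        seg_high = 40000,
                        area_range = c(65, 845),
                        circularity_range = c(0.1, 1.0),
                        intensity_cap = 10000,
                        direct_change_cap = 2000,
                        ratio_cap = 6,
                        background_offset = 100,
                        subtract_background = FALSE,
                        ratio_filter_timepoint = c("before", "both"),
                        intensity_cap_channel = c("donor", "fret", "direct")) {
  cfg <- list(
    wavelength_grid_start = wavelength_grid_start,
    wavelength_grid_end = wavelength_grid_end,
    wavelength_step = wavelength_step,
    pixel_size = pixel_size,
    seed = as.integer(seed),
    guinier_qrg_limit = guinier_qrg_limit,
    forster_r0 = forster_r0,
    seg_low = seg_low,
    seg_high = seg_high,
    area_range = as.numeric(area_range),
    circularity_range = as.numeric(circularity_range),
    intensity_cap = intensity_cap,
    direct_change_cap = direct_change_cap,
    ratio_cap = ratio_cap,
    background_offset = background_offset,
    subtract_background = isTRUE(subtract_background),
    ratio_filter_timepoint = match.arg(ratio_filter_timepoint),
    intensity_cap_channel = match.arg(intensity_cap_channel)
  )
  class(cfg) <- "idrfret_config"
  validate_config(cfg)
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "idrfret_config"))
  if (!(cfg$wavelength_grid_start < cfg$wavelength_grid_end))
    stop("wavelength grid start must be below its end", call. = FALSE)
  if (cfg$wavelength_step <= 0) stop("wavelength_step must be > 0", call. = FALSE)
  pos <- c(pixel_size = cfg$pixel_size, guinier_qrg_limit = cfg$guinier_qrg_limit,
           forster_r0 = cfg$forster_r0, seg_low = cfg$seg_low,
           seg_high = cfg$seg_high, intensity_cap = cfg$intensity_cap,
           direct_change_cap = cfg$direct_change_cap, ratio_cap = cfg$ratio_cap)
  if (any(pos <= 0))
    stop("thresholds must be strictly positive: ",
         paste(names(pos)[pos <= 0], collapse = ", "), call. = FALSE)
  for (nm in c("area_range", "circularity_range")) {
    r <- cfg[[nm]]
    if (length(r) != 2 || any(r <= 0) || r[1] >= r[2])
      stop(nm, " must be an ordered pair of positive values", call. = FALSE)
  }
  cfg
}

#' @export
print.idrfret_config <- function(x, ...) {
  cat("idrfret analysis configuration\n")
  cat(sprintf("  emission grid : %g-%g nm, step %g nm\n",
              x$wavelength_grid_start, x$wavelength_grid_end, x$wavelength_step))
  cat(sprintf("  pixel size    : %g um/px\n", x$pixel_size))
  cat(sprintf("  Guinier q*Rg <= %g;  Forster R0 = %g A\n",
              x$guinier_qrg_limit, x$forster_r0))
  cat(sprintf("  segmentation  : [%g, %g] counts; area [%g, %g] um^2; circ [%g, %g]\n",
              x$seg_low, x$seg_high, x$area_range[1], x$area_range[2],
              x$circularity_range[1], x$circularity_range[2]))
  cat(sprintf("  cell filters  : intensity > %g (%s), |d direct| > %g, ratio > %g\n",
              x$intensity_cap, x$intensity_cap_channel, x$direct_change_cap,
              x$ratio_cap))
  invisible(x)
}

#' Wavelength grid of a configuration
#' @param config An `idrfret_config`.
#' @return Numeric vector of wavelengths in nm.
#' @export
wavelength_grid <- function(config) {
  seq(config$wavelength_grid_start, config$wavelength_grid_end,
      by = config$wavelength_step)
}

#' Write / read a configuration echo
#'
#' Runs that write result tables also write a flat `key = value` echo of the
#' resolved configuration next to them, so every output directory is
#' self-describing.
#' @param config An `idrfret_config`.
#' @param path File path for the echo.
#' @return `write_config` returns `path` invisibly; `read_config` the config.
#' @export
write_config <- function(config, path) {
  validate_config(config)
  keys <- names(config)
  lines <- vapply(keys, function(k) {
    v <- config[[k]]
    sprintf("%s = %s", k, paste(format(v, digits = 15), collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- list()
  for (p in kv) {
    key <- trimws(p[1])
    raw <- strsplit(trimws(paste(p[-1], collapse = "=")), ",", fixed = TRUE)[[1]]
    num <- suppressWarnings(as.numeric(raw))
    lg <- raw %in% c("TRUE", "FALSE")
    vals[[key]] <- if (all(lg)) as.logical(raw) else if (!anyNA(num)) num else raw
  }
  do.call(fret_config, vals)
}

#' Experiment condition descriptor
#'
#' Canonical osmotic labels map to their final osmotic pressures:
#' isosmotic 300 mOsm, hyperosmotic 750 mOsm, hypoosmotic 100 mOsm.
#'
#' @param label One of `"isosmotic"`, `"hyperosmotic"`, `"hypoosmotic"`,
#'   `"custom"`.
#' @param osmolarity Osmolarity in mOsm; inferred from canonical labels.
#' @param solute Optional solute name.
#' @param concentration Optional solute concentration (molar).
#' @return An `experiment_condition` list.
#' @export
experiment_condition <- function(label = c("isosmotic", "hyperosmotic",
                                           "hypoosmotic", "custom"),
                                 osmolarity = NULL, solute = NA_character_,
                                 concentration = NA_real_) {
  label <- match.arg(label)
  canonical <- c(isosmotic = 300, hyperosmotic = 750, hypoosmotic = 100)
  if (is.null(osmolarity)) {
    if (label == "custom")
      stop("custom conditions need an explicit osmolarity", call. = FALSE)
    osmolarity <- canonical[[label]]
  }
  if (osmolarity <= 0) stop("osmolarity must be > 0", call. = FALSE)
  structure(list(label = label, osmolarity = osmolarity, solute = solute,
                 concentration = concentration),
            class = "experiment_condition")
}
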