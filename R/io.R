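#' Emission spectrum container
#'
#' @param wavelengths Strictly increasing wavelengths in nm.
#' @param intensities Intensities in arbitrary units, same length.
#' @param condition Optional [experiment_condition()] or condition label.
#' @param source Optional provenance string (e.g. the file it was read from).
#' @return An `emission_spectrum` object.
#' @export
emission_spectrum <- function(wavelengths, intensities, condition = NULL,
                              source = NA_character_) {
  wavelengths <- as.numeric(wavelengths)
  intensities <- as.numeric(intensities)
  if (length(wavelengths) != length(intensities))
    stop("wavelength and intensity vectors differ in length", call. = FALSE)
  if (any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing", call. = FALSE)
  if (!all(is.finite(intensities)))
    stop("intensities must be finite", call. = FALSE)
  structure(list(wavelengths = wavelengths, intensities = intensities,
                 condition = condition, source = source),
            class = "emission_spectrum")
}

#' @export
print.emission_spectrum <- function(x, ...) {
  cat(sprintf("emission spectrum: %d points, %g-%g nm, peak at %g nm\n",
              length(x$wavelengths), min(x$wavelengths), max(x$wavelengths),
              x$wavelengths[which.max(x$intensities)]))
  invisible(x)
}

sniff_delim <- function(lines) {
  if (any(grepl("\t", lines))) "\t" else ","
}

#' Read an emission spectrum table
#'
#' Reads a two-column wavelength/intensity table (comma- or tab-delimited,
#' header optional) and resamples it onto the configuration wavelength grid
#' by linear interpolation when the grids differ.
#'
#' @param path Path to the table.
#' @param config An [fret_config()]; supplies the target wavelength grid.
#' @return An [emission_spectrum()] on the configuration grid.
#' @export
read_spectrum_table <- function(path, config = fret_config()) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  delim <- sniff_delim(lines)
  first <- strsplit(lines[1], delim, fixed = TRUE)[[1]]
  header <- anyNA(suppressWarnings(as.numeric(first)))
  tab <- utils::read.table(text = paste(lines, collapse = "\n"), sep = delim,
                           header = header)
  if (ncol(tab) < 2) stop("spectrum table needs two columns", call. = FALSE)
  if (nrow(tab) < 10)
    stop("spectrum table has fewer than 10 rows", call. = FALSE)
  wl <- as.numeric(tab[[1]]); iy <- as.numeric(tab[[2]])
  if (anyNA(wl) || anyNA(iy)) stop("non-numeric spectrum entries", call. = FALSE)
  if (any(diff(wl) <= 0))
    stop("wavelengths must be strictly increasing", call. = FALSE)
  grid <- wavelength_grid(config)
  if (length(wl) == length(grid) && max(abs(wl - grid)) < 1e-9) {
    emission_spectrum(grid, iy, source = path)
  } else {
    res <- stats::approx(wl, iy, xout = grid, rule = 2)
    emission_spectrum(grid, res$y, source = path)
  }
}

#' Write an emission spectrum table
#' @param spectrum An [emission_spectrum()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectrum_table <- function(spectrum, path) {
  utils::write.csv(data.frame(wavelength_nm = spectrum$wavelengths,
                              intensity = spectrum$intensities),
                   path, row.names = FALSE)
  invisible(path)
}

#' SAXS profile container
#'
#' @param q Momentum transfer in inverse Angstrom, strictly increasing, > 0.
#' @param I Scattering intensities.
#' @param sigma Per-point uncertainties, strictly positive.
#' @return A `saxs_profile` object.
#' @export
saxs_profile <- function(q, I, sigma) {
  q <- as.numeric(q); I <- as.numeric(I); sigma <- as.numeric(sigma)
  if (length(q) != length(I) || length(q) != length(sigma))
    stop("q, I and sigma must have equal lengths", call. = FALSE)
  if (any(q <= 0) || any(diff(q) <= 0))
    stop("q must be strictly increasing and positive", call. = FALSE)
  if (any(sigma <= 0)) stop("all sigma must be > 0", call. = FALSE)
  structure(list(q = q, I = I, sigma = sigma), class = "saxs_profile")
}

#' @export
print.saxs_profile <- function(x, ...) {
  cat(sprintf("SAXS profile: %d points, q = %.4g-%.4g 1/A\n",
              length(x$q), min(x$q), max(x$q)))
  invisible(x)
}

#' Read / write three-column SAXS text (.dat dialect)
#'
#' Whitespace-delimited `q I sigma` with `#`-prefixed comment lines.  The q
#' unit is fixed to inverse Angstrom; no unit auto-detection is attempted.
#'
#' @param path File path.
#' @return `read_saxs_dat` returns a [saxs_profile()].
#' @export
read_saxs_dat <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  fields <- strsplit(trimws(lines), "\\s+")
  ncols <- lengths(fields)
  if (any(ncols < 3))
    stop("SAXS .dat requires three columns (q, I, sigma)", call. = FALSE)
  num <- vapply(fields, function(f) as.numeric(f[1:3]), numeric(3))
  if (anyNA(num)) stop("non-numeric SAXS entries", call. = FALSE)
  saxs_profile(num[1, ], num[2, ], num[3, ])
}

#' @rdname read_saxs_dat
#' @param profile A [saxs_profile()].
#' @param comment Optional comment line written at the top.
#' @export
write_saxs_dat <- function(profile, path, comment = "q(1/A) I sigma") {
  lines <- c(paste0("# ", comment),
             sprintf("%.10e %.10e %.10e", profile$q, profile$I, profile$sigma))
  writeLines(lines, path)
  invisible(path)
}

#' Three-channel before/after image set
#'
#' Holds the six images of a ratiometric FRET acquisition: donor
#' (donor-ex/donor-em), fret (donor-ex/acceptor-em) and direct
#' (acceptor-ex/acceptor-em) channels, each before and after the osmotic
#' challenge.
#'
#' @param images Named list of numeric matrices: `donor_before`,
#'   `fret_before`, `direct_before`, `donor_after`, `fret_after`,
#'   `direct_after`, identical dimensions.
#' @param pixel_size Pixel size in microns.
#' @return A `cell_image_set` object.
#' @export
cell_image_set <- function(images, pixel_size) {
  need <- as.vector(outer(c("donor", "fret", "direct"),
                          c("before", "after"), paste, sep = "_"))
  if (!all(need %in% names(images)))
    stop("images must contain: ", paste(need, collapse = ", "), call. = FALSE)
  images <- images[need]
  dims <- vapply(images, dim, integer(2))
  if (any(dims != dims[, 1]))
    stop("all six channel images must share dimensions", call. = FALSE)
  structure(list(images = images, pixel_size = pixel_size),
            class = "cell_image_set")
}

#' @export
print.cell_image_set <- function(x, ...) {
  d <- dim(x$images[[1]])
  cat(sprintf("cell image set: %d x %d px, 3 channels x 2 timepoints, %g um/px\n",
              d[1], d[2], x$pixel_size))
  invisible(x)
}

#' Read / write a 6-page TIFF image stack
#'
#' Page order is `donor, fret, direct` for the before timepoint followed by
#' the same three channels after the perturbation (configurable through
#' `page_order`).  Images are 16-bit unsigned raw counts.
#'
#' @param path TIFF path.
#' @param pixel_size Pixel size in microns.
#' @param page_order Character vector naming the six pages.
#' @return `read_image_stack` returns a [cell_image_set()].
#' @export
read_image_stack <- function(path, pixel_size = fret_config()$pixel_size,
                             page_order = c("donor_before", "fret_before",
                                            "direct_before", "donor_after",
                                            "fret_after", "direct_after")) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (length(pages) != 6)
    stop(sprintf("expected a 6-page TIFF, found %d pages", length(pages)),
         call. = FALSE)
  names(pages) <- page_order
  cell_image_set(pages, pixel_size)
}

#' @rdname read_image_stack
#' @param image_set A [cell_image_set()].
#' @export
write_image_stack <- function(image_set, path,
                              page_order = c("donor_before", "fret_before",
                                             "direct_before", "donor_after",
                                             "fret_after", "direct_after")) {
  pages <- lapply(image_set$images[page_order], function(im) {
    im <- pmin(pmax(round(im), 0), 65535)
    im / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  invisible(path)
}
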