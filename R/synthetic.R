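#' Construct specification for synthetic data
#'
#' @param name Construct name.
#' @param idp_length Linker length in residues (a GSX construct has `2 * X`
#'   linker residues).
#' @param true_ef Planted apparent FRET efficiency in `[0, 1]`.
#' @param gs_repeats Optional GS repeat count X; when given, `idp_length`
#'   must equal `2 * gs_repeats`.
#' @return A `construct_spec` list.
#' @export
construct_spec <- function(name, idp_length, true_ef, gs_repeats = NULL) {
  if (idp_length < 0) stop("idp_length must be >= 0", call. = FALSE)
  if (!is.null(gs_repeats) && idp_length != 2 * gs_repeats)
    stop("a GSX construct has 2*X linker residues", call. = FALSE)
  if (true_ef < 0 || true_ef > 1)
    stop("true_ef must lie in [0, 1]", call. = FALSE)
  structure(list(name = name, idp_length = idp_length,
                 gs_repeats = gs_repeats, true_ef = true_ef),
            class = "construct_spec")
}

#' Spectrum noise model
#' @param relative_noise Gaussian noise sd as a fraction of the noiseless
#'   peak intensity.
#' @param baseline Constant additive offset (a.u.).
#' @return A `spectrum_noise` list.
#' @export
spectrum_noise <- function(relative_noise = 0, baseline = 0) {
  if (relative_noise < 0 || baseline < 0)
    stop("noise parameters must be >= 0", call. = FALSE)
  structure(list(relative_noise = relative_noise, baseline = baseline),
            class = "spectrum_noise")
}

# smooth single-peaked emission-like curve: skewed Gaussian with a wider
# red tail, qualitatively matching FP emission line shapes
skew_peak <- function(wl, peak, width_blue, width_red) {
  w <- ifelse(wl < peak, width_blue, width_red)
  exp(-0.5 * ((wl - peak) / w)^2)
}

#' Synthetic donor/acceptor basis spectra
#'
#' Deterministic parametric emission curves (donor maximum near 474 nm,
#' acceptor near 517 nm, mimicking mTurquoise2 and mNeonGreen), area
#' normalized, with quantum yields 0.93 and 0.8 attached.  The exact line
#' shapes are nuisance parameters: downstream analysis uses only peak
#' ordering and area normalization.
#'
#' @param config An [fret_config()] supplying the wavelength grid.
#' @param q_d,q_a Quantum yields to attach.
#' @return A [basis_spectra()].
#' @export
make_basis_spectra <- function(config = fret_config(), q_d = 0.93, q_a = 0.8) {
  wl <- wavelength_grid(config)
  f_d <- skew_peak(wl, 474, 14, 26)
  f_a <- skew_peak(wl, 517, 11, 22)
  basis_spectra(wl, f_d, f_a, q_d = q_d, q_a = q_a)
}

#' Synthesize a construct emission spectrum with planted FRET efficiency
#'
#' Inverts the apparent-efficiency equation: coefficients
#' `F_d = amplitude * (Q_d * rho / Q_a) * (1 - E)` and
#' `F_s = amplitude * E` decompose to exactly `E` under
#' [apparent_fret_efficiency()] with the attached quantum yields.  Gaussian
#' noise (sd = `relative_noise` x noiseless peak) and a constant baseline
#' are then added.
#'
#' @param spec A [construct_spec()] carrying `true_ef`.
#' @param basis A [basis_spectra()].
#' @param amplitude Overall intensity scale (a.u.).
#' @param noise A [spectrum_noise()].
#' @param seed Integer seed.
#' @return An [emission_spectrum()] with the planted truth in
#'   `attr(, "truth")`.
#' @export
synth_construct_spectrum <- function(spec, basis, amplitude = 1000,
                                     noise = spectrum_noise(), seed = 1L) {
  E <- spec$true_ef
  if (E < 0 || E > 1) stop("true_ef must lie in [0, 1]", call. = FALSE)
  k <- basis$q_d * basis$area_ratio / basis$q_a
  F_d <- amplitude * k * (1 - E)
  F_s <- amplitude * E
  clean <- F_d * basis$f_d + F_s * basis$f_a
  set.seed(seed)
  y <- clean + noise$baseline +
    stats::rnorm(length(clean), sd = noise$relative_noise * max(clean, 1e-300))
  out <- emission_spectrum(basis$wavelengths, y, source = "synthetic")
  attr(out, "truth") <- list(true_ef = E, F_d = F_d, F_s = F_s)
  out
}

#' Synthetic SAXS profile with known radius of gyration
#'
#' `guinier_exact`: `I(q) = i0 exp(-rg^2 q^2 / 3)` (the Guinier law holds on
#' the whole grid).  `debye_chain`: the Debye function of an ideal Gaussian
#' chain, `I(q) = i0 * 2 (exp(-x) + x - 1) / x^2` with `x = q^2 rg^2`.
#' Gaussian noise with sd `noise_fraction * I(q)` is added and recorded in
#' the sigma column.
#'
#' @param rg Radius of gyration (Angstrom), > 0.
#' @param i0 Forward scattering intensity.
#' @param model `"guinier_exact"` or `"debye_chain"`.
#' @param q_grid Positive increasing q grid (1/Angstrom).
#' @param noise_fraction Relative noise level.
#' @param seed Integer seed.
#' @return A [saxs_profile()].
#' @export
synth_saxs_profile <- function(rg, i0 = 1, model = c("guinier_exact",
                                                     "debye_chain"),
                               q_grid = seq(0.004, 0.35, by = 0.002),
                               noise_fraction = 0, seed = 1L) {
  model <- match.arg(model)
  if (rg <= 0) stop("rg must be > 0", call. = FALSE)
  if (length(q_grid) == 0) stop("empty q grid", call. = FALSE)
  clean <- switch(model,
    guinier_exact = i0 * exp(-rg^2 * q_grid^2 / 3),
    debye_chain = {
      x <- (q_grid * rg)^2
      i0 * 2 * (exp(-x) + x - 1) / x^2
    })
  sigma <- noise_fraction * clean
  sigma[sigma <= 0] <- 1e-10 * i0  # sigma column must stay positive
  I <- clean
  if (noise_fraction > 0) {
    set.seed(seed)
    I <- clean + stats::rnorm(length(clean), sd = noise_fraction * clean)
  }
  saxs_profile(q_grid, I, sigma)
}

#' Synthetic SEC chromatogram
#'
#' Gaussian elution peak plus white baseline noise on a volume grid.
#'
#' @param peak_center Elution peak position (ml).
#' @param width Gaussian sd (ml), > 0.
#' @param amplitude Peak height (a.u.).
#' @param noise Baseline noise sd (a.u.).
#' @param volume_grid Elution volume grid (ml).
#' @param seed Integer seed.
#' @return A `chromatogram` (list of `volume`, `absorbance`).
#' @export
synth_chromatogram <- function(peak_center, width, amplitude = 1, noise = 0,
                               volume_grid = seq(8, 20, by = 0.02),
                               seed = 1L) {
  if (width <= 0) stop("width must be > 0", call. = FALSE)
  set.seed(seed)
  ab <- amplitude * exp(-0.5 * ((volume_grid - peak_center) / width)^2) +
    stats::rnorm(length(volume_grid), sd = noise)
  chromatogram(volume_grid, ab)
}

#' Chromatogram container
#' @param volume Strictly increasing elution volumes (ml).
#' @param absorbance Absorbance trace (a.u.).
#' @return A `chromatogram` object.
#' @export
chromatogram <- function(volume, absorbance) {
  if (any(diff(volume) <= 0))
    stop("volume must be strictly increasing", call. = FALSE)
  if (length(volume) != length(absorbance))
    stop("volume and absorbance differ in length", call. = FALSE)
  structure(list(volume = volume, absorbance = absorbance),
            class = "chromatogram")
}

#' Synthetic solution-space scan series
#'
#' For each solute and concentration the true efficiency is
#' `clamp(true_ef + slope * concentration, 0, 1)`; spectra are produced with
#' [synth_construct_spectrum()].  The buffer condition (concentration 0) is
#' always included.
#'
#' @param spec A [construct_spec()].
#' @param solutes Named list of concentration vectors (>= 0), one per solute.
#' @param sensitivities Named numeric vector: efficiency change per unit
#'   concentration for each solute.
#' @param basis A [basis_spectra()] (used for every condition).
#' @param amplitude,noise,seed Passed to the spectrum generator.
#' @return A list with `series` (entries of `condition`, `spectrum`, plus
#'   `solute`/`concentration`) and a `truth` data frame.
#' @export
synth_scan_series <- function(spec, solutes, sensitivities, basis,
                              amplitude = 1000, noise = spectrum_noise(),
                              seed = 1L) {
  stopifnot(all(names(solutes) %in% names(sensitivities)))
  series <- list(list(condition = "buffer",
                      spectrum = synth_construct_spectrum(spec, basis,
                        amplitude, noise, seed = seed)))
  truth <- data.frame(condition = "buffer", solute = NA_character_,
                      concentration = 0, true_ef = spec$true_ef)
  i <- 1L
  for (sol in names(solutes)) {
    for (conc in solutes[[sol]]) {
      if (conc < 0) stop("concentrations must be >= 0", call. = FALSE)
      i <- i + 1L
      ef <- min(max(spec$true_ef + sensitivities[[sol]] * conc, 0), 1)
      sp2 <- construct_spec(spec$name, spec$idp_length, ef, spec$gs_repeats)
      lab <- sprintf("%s_%g", sol, conc)
      series[[length(series) + 1L]] <- list(
        condition = lab, solute = sol, concentration = conc,
        spectrum = synth_construct_spectrum(sp2, basis, amplitude, noise,
                                            seed = seed + i))
      truth <- rbind(truth, data.frame(condition = lab, solute = sol,
                                       concentration = conc, true_ef = ef))
    }
  }
  list(series = series, truth = truth)
}
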