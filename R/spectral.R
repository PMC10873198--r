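trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Donor/acceptor basis spectra
#'
#' The spectral unmixing of a dumbbell construct's emission uses the
#' area-normalized emission spectra of the free donor and free acceptor,
#' measured under the same solution condition, together with their quantum
#' yields (0.93 for mTurquoise2, 0.8 for mNeonGreen).
#'
#' @param wavelengths Common wavelength grid (nm).
#' @param f_d,f_a Donor / acceptor emission curves; normalized to unit
#'   trapezoid-rule area on construction.
#' @param q_d,q_a Quantum yields in (0, 1].
#' @return A `basis_spectra` object with an `area_ratio` field (integral of
#'   the stored donor curve over the stored acceptor curve; 1 after
#'   normalization).
#' @export
basis_spectra <- function(wavelengths, f_d, f_a, q_d = 0.93, q_a = 0.8) {
  wavelengths <- as.numeric(wavelengths)
  if (any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing", call. = FALSE)
  if (q_d <= 0 || q_d > 1 || q_a <= 0 || q_a > 1)
    stop("quantum yields must lie in (0, 1]", call. = FALSE)
  ad <- trapz(wavelengths, f_d); aa <- trapz(wavelengths, f_a)
  if (ad <= 0 || aa <= 0) stop("basis curves must have positive area", call. = FALSE)
  f_d <- f_d / ad; f_a <- f_a / aa
  structure(list(wavelengths = wavelengths, f_d = f_d, f_a = f_a,
                 q_d = q_d, q_a = q_a, area_ratio = 1),
            class = "basis_spectra")
}

#' @export
print.basis_spectra <- function(x, ...) {
  cat(sprintf(
    "basis spectra: donor peak %g nm (Qd = %g), acceptor peak %g nm (Qa = %g)\n",
    x$wavelengths[which.max(x$f_d)], x$q_d,
    x$wavelengths[which.max(x$f_a)], x$q_a))
  invisible(x)
}

#' Decompose a construct emission spectrum into donor and acceptor parts
#'
#' Unconstrained linear least squares of the measured spectrum on the two
#' basis curves: `measured ~ F_d * f_d + F_s * f_a`.  `F_d` is the decoupled
#' donor contribution and `F_s` the decoupled (sensitized) acceptor
#' contribution.  Negative coefficients are reported, not clamped; they raise
#' a quality flag.
#'
#' @param measured An [emission_spectrum()] on the basis wavelength grid.
#' @param basis A [basis_spectra()].
#' @return A `fret_decomposition` with fields `F_d`, `F_s`, `residual_rms`,
#'   `ef_app` (`NA` until [apparent_fret_efficiency()] is applied) and
#'   `flags`.
#' @export
decompose_spectrum <- function(measured, basis) {
  if (length(measured$wavelengths) != length(basis$wavelengths) ||
      max(abs(measured$wavelengths - basis$wavelengths)) > 1e-6)
    stop("measured spectrum and basis must share a wavelength grid; resample first",
         call. = FALSE)
  X <- cbind(donor = basis$f_d, acceptor = basis$f_a)
  if (base::kappa(X, exact = TRUE) > 1e8)
    stop("basis curves are collinear; decomposition is degenerate", call. = FALSE)
  fit <- stats::lsfit(X, measured$intensities, intercept = FALSE)
  co <- unname(fit$coefficients)
  res <- fit$residuals
  flags <- character(0)
  if (any(co < 0)) flags <- c(flags, "negative_coefficient")
  structure(list(F_d = co[1], F_s = co[2],
                 residual_rms = sqrt(mean(res^2)),
                 ef_app = NA_real_, flags = flags),
            class = "fret_decomposition")
}

#' @export
print.fret_decomposition <- function(x, ...) {
  cat(sprintf("spectral decomposition: F_d = %.6g, F_s = %.6g, rms = %.3g\n",
              x$F_d, x$F_s, x$residual_rms))
  if (!is.na(x$ef_app)) cat(sprintf("  apparent FRET efficiency = %.6g\n", x$ef_app))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.fret_decomposition <- function(object, ...) {
  c(F_d = object$F_d, F_s = object$F_s)
}

#' Apparent FRET efficiency from a spectral decomposition
#'
#' Implements the quantum-yield-corrected ratiometric estimate
#' `E = 1 - F_d / ((Q_d * rho / Q_a) * F_s + F_d)`, where `rho` is the area
#' ratio of the basis curves as used in the regression (1 for area-normalized
#' bases).  A quality flag (not an error) is raised when the result falls
#' outside `[-0.05, 1.05]`.
#'
#' @param decomp A [decompose_spectrum()] result.
#' @param basis The [basis_spectra()] used for the decomposition.
#' @return The decomposition with `ef_app` filled in.  Use `$ef_app` for the
#'   scalar.
#' @export
apparent_fret_efficiency <- function(decomp, basis) {
  F_d <- decomp$F_d; F_s <- decomp$F_s
  if (F_d == 0 && F_s == 0)
    stop("F_d = F_s = 0: FRET efficiency undefined", call. = FALSE)
  if (F_d + F_s <= 0)
    stop("F_d + F_s must be positive", call. = FALSE)
  k <- basis$q_d * basis$area_ratio / basis$q_a
  ef <- 1 - F_d / (k * F_s + F_d)
  decomp$ef_app <- ef
  if (!is.finite(ef)) stop("non-finite FRET efficiency", call. = FALSE)
  if (ef < -0.05 || ef > 1.05)
    decomp$flags <- union(decomp$flags, "ef_out_of_range")
  decomp
}

#' One-call spectral FRET efficiency
#'
#' Convenience wrapper: decompose and convert in one step.
#' @inheritParams decompose_spectrum
#' @return A completed `fret_decomposition` (with `ef_app`).
#' @export
spectral_fret <- function(measured, basis) {
  apparent_fret_efficiency(decompose_spectrum(measured, basis), basis)
}

#' Fit the glycine-serine repeat calibration standard
#'
#' GS repeats are a model-free length standard: their apparent FRET
#' efficiency decreases linearly with linker length.  The fit is an ordinary
#' least-squares line of efficiency on residue count (2 residues per GS
#' repeat), over per-length averages: replicate measurements at the same
#' length are averaged first, mirroring a fit through the mean points.
#'
#' @param points A data frame with columns `residues` and `ef` (replicates
#'   allowed) and optionally `sd`.
#' @return A `gs_standard_fit` with `slope`, `intercept`, their standard
#'   errors, the 2x2 parameter covariance, `n_points` (distinct lengths) and
#'   the fitted residue range.  Supports `coef`, `predict` (see
#'   [gs_equivalent()]), `print` and `summary`.
#' @export
fit_gs_standard <- function(points) {
  stopifnot(is.data.frame(points), all(c("residues", "ef") %in% names(points)))
  agg <- stats::aggregate(ef ~ residues, data = points, FUN = mean)
  if (nrow(agg) < 3)
    stop("GS standard fit needs at least 3 distinct linker lengths", call. = FALSE)
  fit <- stats::lm(ef ~ residues, data = agg)
  co <- stats::coef(fit)
  # exact linear data triggers lm's perfect-fit warning; handled below
  vc <- suppressWarnings(stats::vcov(fit))
  # exact linear data: residual variance 0 -> parameter errors 0
  if (sum(stats::residuals(fit)^2) < 1e-20) vc[] <- 0
  se <- sqrt(diag(vc))
  structure(list(slope = unname(co[2]), intercept = unname(co[1]),
                 slope_se = unname(se[2]), intercept_se = unname(se[1]),
                 covariance = vc, n_points = nrow(agg),
                 residue_range = range(agg$residues),
                 points = agg, lm = fit),
            class = "gs_standard_fit")
}

#' @export
print.gs_standard_fit <- function(x, ...) {
  cat(sprintf(
    "GS-repeat standard: E = %.5g %+.5g * residues  (n = %d lengths, %g-%g aa)\n",
    x$intercept, x$slope, x$n_points, x$residue_range[1], x$residue_range[2]))
  cat(sprintf("  slope se = %.3g, intercept se = %.3g\n", x$slope_se, x$intercept_se))
  invisible(x)
}

#' @export
coef.gs_standard_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
summary.gs_standard_fit <- function(object, ...) summary(object$lm, ...)

#' @export
predict.gs_standard_fit <- function(object, residues, ...) {
  gs_equivalent(object, residues)
}

#' Interpolated GS-equivalent efficiency at a given linker length
#'
#' Evaluates the fitted GS line at `residues` residues and propagates the
#' parameter covariance: `Var(E) = Var(b) + x^2 Var(m) + 2 x Cov(b, m)`.
#' Lengths outside the fitted range are returned with an extrapolation flag.
#'
#' @param fit A [fit_gs_standard()] result.
#' @param residues Residue count(s), >= 0.
#' @return A data frame with `residues`, `ef`, `se`, `extrapolated`.
#' @export
gs_equivalent <- function(fit, residues) {
  stopifnot(inherits(fit, "gs_standard_fit"), all(residues >= 0))
  vc <- fit$covariance
  ef <- fit$intercept + fit$slope * residues
  v <- vc[1, 1] + residues^2 * vc[2, 2] + 2 * residues * vc[1, 2]
  data.frame(residues = residues, ef = ef, se = sqrt(pmax(v, 0)),
             extrapolated = residues < fit$residue_range[1] |
                            residues > fit$residue_range[2])
}

#' Classify an IDP efficiency against its GS-equivalent baseline
#'
#' Higher apparent efficiency at matched length means shorter average
#' donor-acceptor separation, i.e. a more compact ensemble.  The call is
#' `compact` when the IDP exceeds the baseline by more than `k` combined
#' standard errors (root-sum-square), `expanded` when below by the same
#' margin, otherwise `indistinguishable`.
#'
#' @param e_idp,sd_idp IDP efficiency and its uncertainty.
#' @param e_baseline,sd_baseline GS-equivalent baseline and uncertainty.
#' @param k Margin in combined standard errors (default 1).
#' @param tol Absolute numerical tolerance on the difference, so that
#'   floating-point fuzz on error-free inputs does not flip the call.
#' @return `"compact"`, `"expanded"` or `"indistinguishable"`.
#' @export
classify_vs_gs <- function(e_idp, sd_idp, e_baseline, sd_baseline, k = 1,
                           tol = 1e-9) {
  stopifnot(sd_idp >= 0, sd_baseline >= 0)
  comb <- sqrt(sd_idp^2 + sd_baseline^2)
  d <- e_idp - e_baseline
  if (d > k * comb + tol) "compact"
  else if (d < -(k * comb + tol)) "expanded"
  else "indistinguishable"
}

#' Solution-space scan analysis
#'
#' A solution space scan measures how the apparent FRET efficiency of a
#' construct responds to a panel of solutes.  Each condition's spectra are
#' decomposed with that condition's own basis spectra (free-fluorophore
#' spectra re-measured in the same solution, correcting solute effects on
#' emission), and efficiencies are reported as changes from the buffer
#' condition.  When a per-condition GS standard is supplied, the scan also
#' reports the deviation of the construct's response from the GS-equivalent
#' response at matched length and a sensitivity call per condition.
#'
#' @param series A list of entries, each a list with `condition` (character
#'   label) and `spectrum` (an [emission_spectrum()]); replicate entries with
#'   the same label are aggregated (mean and sd over replicate
#'   decompositions).
#' @param bases Named list of [basis_spectra()], one per condition label.
#' @param buffer Label of the reference condition (must be present).
#' @param gs_fits Optional named list of [fit_gs_standard()] per condition.
#' @param idp_residues Linker length at which GS baselines are interpolated.
#' @param k Sensitivity margin in combined standard errors.
#' @return A `scan_result`: data frame with per-condition `ef`, `sd`,
#'   `delta_ef` (0 in buffer by construction) and, when GS fits are given,
#'   `gs_delta`, `gs_delta_se`, `deviation` and `sensitivity_call`.
#' @export
solution_scan <- function(series, bases, buffer = "buffer", gs_fits = NULL,
                          idp_residues = NULL, k = 1) {
  labs <- vapply(series, function(s) s$condition, character(1))
  if (!buffer %in% labs)
    stop("scan series must contain the buffer condition", call. = FALSE)
  conds <- unique(labs)
  per <- lapply(conds, function(cl) {
    if (is.null(bases[[cl]]))
      stop("no basis spectra for condition: ", cl, call. = FALSE)
    efs <- vapply(series[labs == cl], function(s)
      spectral_fret(s$spectrum, bases[[cl]])$ef_app, numeric(1))
    c(ef = mean(efs), sd = if (length(efs) > 1) stats::sd(efs) else 0)
  })
  per <- do.call(rbind, per)
  out <- data.frame(condition = conds, ef = per[, "ef"], sd = per[, "sd"],
                    row.names = NULL)
  ib <- match(buffer, conds)
  out$delta_ef <- out$ef - out$ef[ib]
  out$delta_ef[ib] <- 0  # exact by definition
  if (!is.null(gs_fits)) {
    if (is.null(idp_residues))
      stop("idp_residues is required when GS fits are supplied", call. = FALSE)
    gb <- gs_equivalent(gs_fits[[buffer]], idp_residues)
    gs <- t(vapply(conds, function(cl) {
      g <- gs_equivalent(gs_fits[[cl]], idp_residues)
      c(d = g$ef - gb$ef, se = sqrt(g$se^2 + gb$se^2))
    }, numeric(2)))
    out$gs_delta <- gs[, 1]; out$gs_delta_se <- gs[, 2]
    out$gs_delta[ib] <- 0
    out$deviation <- out$delta_ef - out$gs_delta
    out$sensitivity_call <- vapply(seq_len(nrow(out)), function(i) {
      cl <- classify_vs_gs(out$delta_ef[i], out$sd[i],
                           out$gs_delta[i], out$gs_delta_se[i], k = k)
      switch(cl, compact = "more_sensitive", expanded = "less_sensitive",
             "indistinguishable")
    }, character(1))
    out$sensitivity_call[ib] <- "indistinguishable"
  }
  class(out) <- c("scan_result", "data.frame")
  attr(out, "buffer") <- buffer
  out
}
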