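test_that("decomposition recovers exact and noisy mixing coefficients", {
  bs <- default_basis
  wl <- bs$wavelengths

  m <- emission_spectrum(wl, 2.0 * bs$f_d)
  d <- decompose_spectrum(m, bs)
  expect_equal(d$F_d, 2.0, tolerance = 1e-10)
  expect_equal(d$F_s, 0, tolerance = 1e-10)

  z <- decompose_spectrum(emission_spectrum(wl, rep(0, length(wl))), bs)
  expect_equal(unname(coef(z)), c(0, 0))
  expect_equal(z$residual_rms, 0)

  # noisy mixture: truth (1.5, 3.0), noise 0.1% of peak
  clean <- 1.5 * bs$f_d + 3.0 * bs$f_a
  set.seed(17)
  noisy <- emission_spectrum(wl, clean + rnorm(length(wl),
                                               sd = 0.001 * max(clean)))
  dn <- decompose_spectrum(noisy, bs)
  expect_equal(dn$F_d, 1.5, tolerance = 0.01)
  expect_equal(dn$F_s, 3.0, tolerance = 0.01)
  # oracle: direct normal-equations solve must agree with the fit
  X <- cbind(bs$f_d, bs$f_a)
  beta <- solve(t(X) %*% X, t(X) %*% noisy$intensities)
  expect_equal(unname(coef(dn)), as.vector(beta), tolerance = 1e-8)

  # collinear basis is degenerate
  bad <- bs; bad$f_a <- bs$f_d
  expect_error(decompose_spectrum(m, bad), "collinear")
})

test_that("apparent efficiency obeys its limits and the printed arithmetic", {
  bs <- default_basis
  mk <- function(fd, fs) structure(
    list(F_d = fd, F_s = fs, residual_rms = 0, ef_app = NA_real_,
         flags = character(0)), class = "fret_decomposition")
  expect_equal(apparent_fret_efficiency(mk(3, 0), bs)$ef_app, 0)
  expect_equal(apparent_fret_efficiency(mk(0, 3), bs)$ef_app, 1)
  # F_d = F_s = 1 with Qd = 0.93, Qa = 0.8: 1 - 1/(1.1625 + 1)
  expect_equal(apparent_fret_efficiency(mk(1, 1), bs)$ef_app,
               1 - 1 / (0.93 / 0.8 + 1), tolerance = 1e-12)
  expect_equal(apparent_fret_efficiency(mk(1, 1), bs)$ef_app, 0.5376,
               tolerance = 1e-4)
  expect_error(apparent_fret_efficiency(mk(0, 0), bs), "undefined")
  # out-of-range efficiencies flag, not error
  fl <- apparent_fret_efficiency(mk(-0.5, 3), bs)
  expect_true("ef_out_of_range" %in% fl$flags)
})

test_that("efficiency is monotone in the coefficients and amplitude-invariant", {
  bs <- default_basis
  mk <- function(fd, fs) structure(
    list(F_d = fd, F_s = fs, residual_rms = 0, ef_app = NA_real_,
         flags = character(0)), class = "fret_decomposition")
  fs_grid <- seq(0.1, 5, length.out = 20)
  e_up <- vapply(fs_grid, function(fs)
    apparent_fret_efficiency(mk(1, fs), bs)$ef_app, numeric(1))
  expect_true(all(diff(e_up) > 0))
  fd_grid <- seq(0.1, 5, length.out = 20)
  e_dn <- vapply(fd_grid, function(fd)
    apparent_fret_efficiency(mk(fd, 1), bs)$ef_app, numeric(1))
  expect_true(all(diff(e_dn) < 0))

  sp <- synth_construct_spectrum(construct_spec("a", 0, 0.37), bs, seed = 2)
  e1 <- spectral_fret(sp, bs)$ef_app
  sp$intensities <- 17.3 * sp$intensities
  expect_equal(spectral_fret(sp, bs)$ef_app, e1, tolerance = 1e-12)
})

test_that("GS standard fit reproduces exact lines and resists symmetric noise", {
  res <- c(0, 16, 32, 48, 64, 96)
  exact <- data.frame(residues = res, ef = 0.5 - 0.005 * res)
  fit <- fit_gs_standard(exact)
  expect_equal(fit$slope, -0.005, tolerance = 1e-12)
  expect_equal(fit$intercept, 0.5, tolerance = 1e-12)
  expect_equal(fit$slope_se, 0)
  expect_equal(fit$intercept_se, 0)
  expect_equal(fit$n_points, 6)

  # symmetric +/- eps noise on alternating points leaves the slope alone
  # when the design is balanced in x (use equally spaced lengths)
  res2 <- c(0, 16, 32, 48)
  base <- 0.5 - 0.005 * res2
  pert <- base + c(1, -1, -1, 1) * 0.01
  f2 <- fit_gs_standard(data.frame(residues = res2, ef = pert))
  expect_equal(f2$slope, -0.005, tolerance = 1e-12)

  expect_error(fit_gs_standard(data.frame(residues = c(0, 16),
                                          ef = c(0.5, 0.4))),
               "3 distinct")
  # replicates are averaged before fitting (fit of the averages)
  reps <- data.frame(residues = rep(res, each = 2),
                     ef = rep(0.5 - 0.005 * res, each = 2) + c(-0.02, 0.02))
  fr <- fit_gs_standard(reps)
  expect_equal(fr$slope, -0.005, tolerance = 1e-12)
})

test_that("GS standard recovers a generating line across noise seeds", {
  # with 6 lengths the slope se has 4 df, so the calibrated 95% interval
  # uses the t quantile; the plain 2-se band covers slightly less
  res <- c(8, 16, 24, 32, 48, 64) * 2
  tcrit <- qt(0.975, df = 4)
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    ef <- 0.55 - 0.003 * res + rnorm(length(res), sd = 0.01)
    f <- fit_gs_standard(data.frame(residues = res, ef = ef))
    c(t = abs(f$slope - (-0.003)) <= tcrit * f$slope_se,
      two = abs(f$slope - (-0.003)) <= 2 * f$slope_se)
  }, logical(2))
  expect_gte(mean(hits["t", ]), 0.90)
  expect_gte(mean(hits["two", ]), 0.80)
})

test_that("GS-equivalent interpolation propagates errors and flags range", {
  res <- c(0, 16, 32, 48, 64, 96)
  fit <- fit_gs_standard(data.frame(residues = res, ef = 0.5 - 0.005 * res))
  g0 <- gs_equivalent(fit, 0)
  expect_equal(g0$ef, fit$intercept)
  expect_equal(g0$se, fit$intercept_se)
  g34 <- gs_equivalent(fit, 34)
  expect_equal(g34$ef, 0.5 - 0.005 * 34)   # = 0.33 exactly
  expect_equal(g34$ef, 0.33)
  expect_equal(g34$se, 0)
  expect_false(g34$extrapolated)
  expect_true(gs_equivalent(fit, 200)$extrapolated)
  # predict method is the same interpolation
  expect_equal(predict(fit, 34)$ef, 0.33)
  # interpolation consistency: a fitted point reproduces its fitted value
  expect_equal(gs_equivalent(fit, 32)$ef, 0.5 - 0.005 * 32)
})

test_that("compaction calls respect the combined-error margin", {
  expect_equal(classify_vs_gs(0.4, 0.01, 0.4, 0.01), "indistinguishable")
  comb <- sqrt(2) * 0.01
  expect_equal(classify_vs_gs(0.4 + 10 * comb, 0.01, 0.4, 0.01), "compact")
  expect_equal(classify_vs_gs(0.4 - 10 * comb, 0.01, 0.4, 0.01), "expanded")
  expect_error(classify_vs_gs(0.4, -0.01, 0.4, 0.01), "sd")
})

test_that("solution scans anchor the buffer at zero and see planted slopes", {
  bs <- default_basis
  spec <- construct_spec("idp", 34, 0.4)
  out <- synth_scan_series(spec,
                           solutes = list(ficoll = c(0.5, 1),
                                          urea = c(0.5, 1)),
                           sensitivities = c(ficoll = 0.08, urea = 0),
                           basis = bs, seed = 12)
  bases <- setNames(rep(list(bs), nrow(out$truth)), out$truth$condition)
  sc <- solution_scan(out$series, bases, buffer = "buffer")
  expect_equal(sc$delta_ef[sc$condition == "buffer"], 0)
  ficoll <- sc[grepl("ficoll", sc$condition), ]
  expect_equal(ficoll$delta_ef, 0.08 * c(0.5, 1), tolerance = 1e-9)
  urea <- sc[grepl("urea", sc$condition), ]
  expect_equal(urea$delta_ef, c(0, 0), tolerance = 1e-9)
  expect_error(solution_scan(out$series[-1], bases), "buffer")
})

test_that("an IDP identical to the GS series deviates nowhere", {
  bs <- default_basis
  res <- c(16, 32, 48, 64, 96)
  mkfit <- function(shift) fit_gs_standard(
    data.frame(residues = res, ef = 0.5 - 0.004 * res + shift))
  gs_fits <- list(buffer = mkfit(0), solute = mkfit(0.03))
  # IDP response equals the GS response at 34 residues in every condition
  idp_buffer <- gs_equivalent(gs_fits$buffer, 34)$ef
  idp_solute <- gs_equivalent(gs_fits$solute, 34)$ef
  series <- list(
    list(condition = "buffer", spectrum = synth_construct_spectrum(
      construct_spec("i", 34, idp_buffer), bs, seed = 1)),
    list(condition = "solute", spectrum = synth_construct_spectrum(
      construct_spec("i", 34, idp_solute), bs, seed = 2)))
  sc <- solution_scan(series, list(buffer = bs, solute = bs),
                      gs_fits = gs_fits, idp_residues = 34)
  expect_equal(sc$deviation, c(0, 0), tolerance = 1e-9)
  expect_true(all(sc$sensitivity_call == "indistinguishable"))
})

test_that("round trip holds for every efficiency on a grid", {
  bs <- default_basis
  for (E in seq(0, 1, by = 0.1)) {
    sp <- synth_construct_spectrum(construct_spec("a", 0, E), bs, seed = 1)
    expect_equal(spectral_fret(sp, bs)$ef_app, E, tolerance = 1e-9)
  }
})
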