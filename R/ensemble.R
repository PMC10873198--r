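#' Coarse-grained dumbbell model parameters
#'
#' One bead per linker residue on a freely jointed chain with 3.8 Angstrom
#' bonds, flanked by two rigid fluorescent-protein spheres of 16 Angstrom
#' radius.  Non-adjacent linker beads attract through a square well of depth
#' `attraction_scale * epsilon0` (kT) within `contact_range`; the FP spheres
#' interact through excluded volume only, so attraction stays intra-linker.
#'
#' @param n_linker_residues Linker length in residues (>= 0).
#' @param attraction_scale Dimensionless attraction strength `s` (the sweep
#'   convention runs 0.30 for a random coil to 0.62 for a compact globule).
#' @param n_conformers Conformers to record.
#' @param mc_steps Monte Carlo moves between recorded conformers.
#' @param equilibration_steps Moves discarded before sampling.
#' @param bond_length,bead_radius,fp_radius,contact_range Geometry in
#'   Angstrom.
#' @param epsilon0 Well depth at `s = 1`, in kT.
#' @param fp_mass Scattering/inertial mass of each FP sphere relative to one
#'   linker residue (mTurquoise2/mNeonGreen are roughly 230 residues).
#' @param seed Integer seed.
#' @return A `dumbbell_params` list.
#' @export
dumbbell_params <- function(n_linker_residues, attraction_scale = 0,
                            n_conformers = 500, mc_steps = 400,
                            equilibration_steps = 5000, bond_length = 3.8,
                            bead_radius = 1.9, fp_radius = 16,
                            contact_range = 6, epsilon0 = 1, fp_mass = 230,
                            seed = 1L) {
  if (n_linker_residues < 0) stop("n_linker_residues must be >= 0", call. = FALSE)
  if (attraction_scale < 0) stop("attraction_scale must be >= 0", call. = FALSE)
  if (any(c(bond_length, bead_radius, fp_radius, contact_range) <= 0))
    stop("all lengths must be > 0", call. = FALSE)
  structure(list(n_linker_residues = as.integer(n_linker_residues),
                 attraction_scale = attraction_scale,
                 n_conformers = as.integer(n_conformers),
                 mc_steps = as.integer(mc_steps),
                 equilibration_steps = as.integer(equilibration_steps),
                 bond_length = bond_length, bead_radius = bead_radius,
                 fp_radius = fp_radius, contact_range = contact_range,
                 epsilon0 = epsilon0, fp_mass = fp_mass,
                 seed = as.integer(seed)),
            class = "dumbbell_params")
}

#' Sample a dumbbell conformer ensemble
#'
#' Metropolis Monte Carlo with bond-preserving pivot and crankshaft moves on
#' the excluded-volume chain described by [dumbbell_params()].  Conformers
#' are recorded every `mc_steps` accepted-or-rejected moves after the
#' equilibration phase.  Reproducible: the same parameters and seed give a
#' bitwise-identical ensemble.
#'
#' @param params A [dumbbell_params()].
#' @param keep_coords Keep full coordinates (needed for scattering).
#' @return A `dumbbell_ensemble`: vectors `re` (FP center-to-center
#'   distance), `re_linker` (first-to-last linker bead distance, the
#'   observable that shows pure excluded-volume chain scaling, since `re`
#'   additionally carries the length-independent FP geometry) and `rg`
#'   (mass-weighted radius of gyration, FP spheres as uniform spheres),
#'   Monte Carlo `acceptance`, and a `coords` array
#'   (`n_sites x 3 x n_conformers`) when requested.
#' @export
sample_dumbbell_ensemble <- function(params, keep_coords = TRUE) {
  stopifnot(inherits(params, "dumbbell_params"))
  set.seed(params$seed)
  out <- .dumbbell_mc(params$n_linker_residues, params$attraction_scale,
                      params$epsilon0, params$bond_length,
                      params$bead_radius, params$fp_radius,
                      params$contact_range, params$fp_mass,
                      params$n_conformers, params$mc_steps,
                      params$equilibration_steps, keep_coords)
  out$params <- params
  class(out) <- "dumbbell_ensemble"
  out
}

#' @export
print.dumbbell_ensemble <- function(x, ...) {
  cat(sprintf(
    "dumbbell ensemble: %d conformers, %d linker residues, s = %g\n",
    length(x$re), x$params$n_linker_residues, x$params$attraction_scale))
  cat(sprintf("  <Re> = %.1f A, <Rg> = %.1f A, MC acceptance = %.2f\n",
              mean(x$re), mean(x$rg), x$acceptance))
  invisible(x)
}

#' Debye forward scattering of a conformer ensemble
#'
#' Per conformer, the Debye double sum over scattering centers: each linker
#' bead is a point scatterer of unit mass and each FP sphere contributes the
#' uniform-sphere form factor with mass `fp_mass`; cross terms use
#' center-to-center distances.  `I(0)` equals the squared total scattering
#' mass.  The ensemble curve is the mean over conformers.
#'
#' @param ensemble A [sample_dumbbell_ensemble()] result with coordinates.
#' @param q_grid Positive q grid (1/Angstrom).
#' @return A list with `q`, `mean_I` (ensemble average), and `I` (conformers
#'   x q matrix).
#' @export
debye_scattering <- function(ensemble, q_grid = seq(0.004, 0.25, by = 0.004)) {
  if (length(q_grid) == 0) stop("empty q grid", call. = FALSE)
  if (is.null(ensemble$coords))
    stop("ensemble was sampled without coordinates", call. = FALSE)
  if (length(ensemble$re) == 0) stop("empty ensemble", call. = FALSE)
  p <- ensemble$params
  N <- dim(ensemble$coords)[1]
  masses <- rep(1, N); radii <- rep(0, N)
  masses[c(1, N)] <- p$fp_mass
  radii[c(1, N)] <- p$fp_radius
  I <- .debye_profiles(ensemble$coords, masses, radii, q_grid)
  list(q = q_grid, mean_I = colMeans(I), I = I)
}

#' Forster efficiency of a donor-acceptor separation
#'
#' `E = R0^6 / (R0^6 + r^6)`; strictly decreasing in `r`, mapping 0 to 1 and
#' the Forster distance `R0` to one half.
#'
#' @param r_e End-to-end (FP center) distance(s), Angstrom, >= 0.
#' @param r0 Forster distance (default 62 Angstrom for
#'   mTurquoise2--mNeonGreen).
#' @return Efficiency in (0, 1].
#' @export
forster_efficiency <- function(r_e, r0 = 62) {
  if (any(r_e < 0)) stop("r_e must be >= 0", call. = FALSE)
  if (r0 <= 0) stop("r0 must be > 0", call. = FALSE)
  # 1 / (1 + (r/R0)^6) is overflow-safe for large r
  1 / (1 + (r_e / r0)^6)
}

#' Ensemble FRET summary
#'
#' Converts every conformer's end-to-end distance to an efficiency and
#' reports the mean together with the central 50 percent (25th--75th
#' percentile) interval of the per-conformer values.
#'
#' @param ensemble A `dumbbell_ensemble` (or anything with an `re` field).
#' @param r0 Forster distance in Angstrom.
#' @return A list with `mean_ef`, `central50`, and the per-conformer `ef`.
#' @export
ensemble_fret_summary <- function(ensemble, r0 = 62) {
  if (length(ensemble$re) == 0) stop("empty ensemble", call. = FALSE)
  ef <- forster_efficiency(ensemble$re, r0)
  list(mean_ef = mean(ef),
       central50 = unname(stats::quantile(ef, c(0.25, 0.75), type = 7)),
       ef = ef)
}

#' Simulation campaign plan arithmetic
#'
#' The published sweep runs every GS linker length against every attraction
#' scale: lengths {8, 16, 24, 32, 48} repeats, scales 0.30 to 0.62 in steps
#' of 0.02, 1,000 independent simulations per combination, each of 100,000
#' Monte Carlo steps with the first 50,000 discarded and conformations
#' sampled every 5,000 steps.
#'
#' @param gs_lengths GS repeat counts.
#' @param scale_start,scale_end,scale_step Attraction-scale sweep.
#' @param sims_per_combo Independent simulations per length/scale pair.
#' @param steps_per_sim,equilibration,sample_interval Per-simulation
#'   schedule (Monte Carlo steps).
#' @return A `campaign_plan` list.
#' @export
campaign_plan <- function(gs_lengths = c(8, 16, 24, 32, 48),
                          scale_start = 0.30, scale_end = 0.62,
                          scale_step = 0.02, sims_per_combo = 1000,
                          steps_per_sim = 100000, equilibration = 50000,
                          sample_interval = 5000) {
  structure(list(gs_lengths = gs_lengths, scale_start = scale_start,
                 scale_end = scale_end, scale_step = scale_step,
                 sims_per_combo = sims_per_combo,
                 steps_per_sim = steps_per_sim,
                 equilibration = equilibration,
                 sample_interval = sample_interval),
            class = "campaign_plan")
}

#' @rdname campaign_plan
#' @param plan A `campaign_plan`.
#' @param scale_factor Integer divisor applied to `sims_per_combo` and the
#'   per-simulation schedule to derive a scaled-down campaign with the same
#'   structure.
#' @return For `plan_campaign`: a list of derived counts `samples_per_sim`,
#'   `conformers_per_combo`, `n_scales`, `n_lengths`, `total_sims`,
#'   `total_conformers`.
#' @export
plan_campaign <- function(plan = campaign_plan(), scale_factor = 1) {
  p <- plan
  if (scale_factor != 1) {
    p$sims_per_combo <- p$sims_per_combo / scale_factor
    p$steps_per_sim <- p$steps_per_sim / scale_factor
    p$equilibration <- p$equilibration / scale_factor
    p$sample_interval <- p$sample_interval / scale_factor
  }
  span <- p$steps_per_sim - p$equilibration
  if (span <= 0 || span %% p$sample_interval != 0)
    stop("sampling interval must divide the post-equilibration span",
         call. = FALSE)
  n_scales <- round((p$scale_end - p$scale_start) / p$scale_step) + 1
  if (abs(p$scale_start + (n_scales - 1) * p$scale_step - p$scale_end) > 1e-9)
    stop("scale_step must divide the scale range", call. = FALSE)
  samples_per_sim <- span / p$sample_interval
  conformers_per_combo <- p$sims_per_combo * samples_per_sim
  total_sims <- length(p$gs_lengths) * n_scales * p$sims_per_combo
  list(samples_per_sim = samples_per_sim,
       conformers_per_combo = conformers_per_combo,
       n_scales = n_scales, n_lengths = length(p$gs_lengths),
       total_sims = total_sims,
       total_conformers = total_sims * samples_per_sim)
}

#' Select a SAXS-matched subensemble
#'
#' Greedy stochastic exchange: starting from a random subset of the given
#' size, repeatedly propose swapping one member for one non-member and
#' accept the swap when the chi-square-free of the subset-average curve
#' against the target improves.  The objective is evaluated on a fixed set
#' of Shannon-channel draws (frozen from the seed) so accepted swaps are
#' monotone improvements; the returned `chi2_free` is recomputed on the
#' final subset with [chi2_free()] at `n_rounds` rounds.
#'
#' @param pool_I Conformer scattering curves, conformers x q matrix (e.g.
#'   `debye_scattering(...)$I`).
#' @param target A [saxs_profile()] on the same q grid.
#' @param size Subensemble size (published choice: 1,000).
#' @param seed Integer seed.
#' @param max_sweeps Stop after this many sweeps (of `size` proposals each)
#'   without improvement, or `10 * max_sweeps` sweeps in total.
#' @param n_rounds Rounds for the reported final chi-square-free.
#' @param d_max Optional maximum dimension for the Shannon channel count.
#' @return A `subensemble_result`: `selected` (indices), `size`,
#'   `chi2_free`, `objective_trace`, `seed`.
#' @export
select_subensemble <- function(pool_I, target, size, seed = 1L,
                               max_sweeps = 100, n_rounds = 500,
                               d_max = NULL) {
  n_pool <- nrow(pool_I)
  if (size > n_pool) stop("size exceeds pool size", call. = FALSE)
  if (ncol(pool_I) != length(target$q))
    stop("pool curves and target must share the q grid", call. = FALSE)
  if (is.null(d_max)) d_max <- 3 * guinier_fit(target)$rg
  n_channels <- max(2, ceiling(max(target$q) * d_max / pi))
  edges <- seq(min(target$q), max(target$q), length.out = n_channels + 1)
  ch <- findInterval(target$q, edges, rightmost.closed = TRUE)
  idx_by_ch <- split(seq_along(target$q), ch)
  idx_by_ch <- idx_by_ch[lengths(idx_by_ch) > 0]

  set.seed(seed)
  # frozen draw set: one point per channel per round, reused for every
  # objective evaluation so the search is monotone and deterministic
  n_obj_rounds <- 32L
  draws <- replicate(n_obj_rounds, vapply(idx_by_ch, function(ii)
    if (length(ii) == 1) ii else ii[sample.int(length(ii), 1)], integer(1)))
  d <- target$I; s <- target$sigma
  objective <- function(mean_I) {
    chis <- apply(draws, 2, function(pick) {
      m <- mean_I[pick]
      c0 <- sum(m * d[pick] / s[pick]^2) / sum(m^2 / s[pick]^2)
      sum(((c0 * m - d[pick]) / s[pick])^2) / (length(pick) - 1)
    })
    stats::median(chis)
  }

  if (size == n_pool) {
    sel <- seq_len(n_pool)
    final <- chi2_free(colMeans(pool_I), target, n_rounds = n_rounds,
                       seed = seed, d_max = d_max)
    return(structure(list(selected = sel, size = size,
                          chi2_free = final$chi2_free,
                          objective_trace = objective(colMeans(pool_I)),
                          seed = as.integer(seed)),
                     class = "subensemble_result"))
  }

  sel <- sample.int(n_pool, size)
  in_sel <- logical(n_pool); in_sel[sel] <- TRUE
  sum_I <- colSums(pool_I[sel, , drop = FALSE])
  best <- objective(sum_I / size)
  trace <- best
  sweeps_since_improve <- 0L
  total_sweeps <- 0L
  while (sweeps_since_improve < max_sweeps && total_sweeps < 10 * max_sweeps) {
    improved <- FALSE
    for (prop in seq_len(size)) {
      out_i <- sel[sample.int(size, 1)]
      cand <- which(!in_sel)
      in_i <- cand[sample.int(length(cand), 1)]
      new_sum <- sum_I - pool_I[out_i, ] + pool_I[in_i, ]
      val <- objective(new_sum / size)
      if (val < best) {
        best <- val
        sum_I <- new_sum
        in_sel[out_i] <- FALSE; in_sel[in_i] <- TRUE
        sel[sel == out_i] <- in_i
        improved <- TRUE
        trace <- c(trace, val)
      }
    }
    total_sweeps <- total_sweeps + 1L
    sweeps_since_improve <- if (improved) 0L else sweeps_since_improve + 1L
  }
  final <- chi2_free(sum_I / size, target, n_rounds = n_rounds, seed = seed,
                     d_max = d_max)
  structure(list(selected = sort(sel), size = size,
                 chi2_free = final$chi2_free, objective_trace = trace,
                 seed = as.integer(seed)),
            class = "subensemble_result")
}

#' @export
print.subensemble_result <- function(x, ...) {
  cat(sprintf("subensemble: %d conformers selected, chi2_free = %.4g (seed %d)\n",
              x$size, x$chi2_free, x$seed))
  invisible(x)
}

#' Write / read a conformer ensemble as plain-text xyz frames
#'
#' One block per conformer: a site-count line, a comment line with `re` and
#' `rg`, then `x y z` rows.
#'
#' @param ensemble A `dumbbell_ensemble` with coordinates.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ensemble_xyz <- function(ensemble, path) {
  if (is.null(ensemble$coords)) stop("no coordinates to write", call. = FALSE)
  dims <- dim(ensemble$coords)
  con <- file(path, "w")
  on.exit(close(con))
  for (c_i in seq_len(dims[3])) {
    writeLines(as.character(dims[1]), con)
    writeLines(sprintf("# re %.8g rg %.8g", ensemble$re[c_i],
                       ensemble$rg[c_i]), con)
    xyz <- ensemble$coords[, , c_i]
    writeLines(sprintf("%.8g %.8g %.8g", xyz[, 1], xyz[, 2], xyz[, 3]), con)
  }
  invisible(path)
}
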