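test_that("registration recovers planted rigid transforms", {
  sim <- synth_cell_image_pair(12, seed = 3, img_dim = c(256, 256),
                               shift = c(3, -2), rotation_deg = 0)
  reg <- register_rigid(sim$images)
  tr <- attr(reg, "transform")
  expect_equal(unname(tr$shift), c(-3, 2), tolerance = 0.2)

  # identity: no shift, no rotation
  sim0 <- synth_cell_image_pair(12, seed = 3, img_dim = c(256, 256),
                                shift = c(0, 0), rotation_deg = 0)
  tr0 <- attr(register_rigid(sim0$images), "transform")
  expect_equal(unname(tr0$shift), c(0, 0), tolerance = 0.1)
  expect_equal(tr0$rotation, 0, tolerance = 0.1)

  # with rotation: both components recovered
  simr <- synth_cell_image_pair(12, seed = 4, img_dim = c(256, 256),
                                shift = c(4, 1), rotation_deg = 1.5)
  trr <- attr(register_rigid(simr$images), "transform")
  expect_equal(trr$rotation, -1.5, tolerance = 0.3)
  expect_equal(unname(trr$shift), c(-4, -1), tolerance = 0.5)

  # uncorrelated noise cannot be registered
  set.seed(1)
  a <- matrix(runif(64^2), 64); b <- matrix(runif(64^2), 64)
  noise_set <- cell_image_set(list(donor_before = a, fret_before = a,
                                   direct_before = a, donor_after = b,
                                   fret_after = b, direct_after = b), 0.65)
  expect_error(register_rigid(noise_set), "registration failed")
})

test_that("segmentation thresholds, splits and labels disk cells", {
  cfg <- fret_config()
  # all pixels below threshold: no labels
  expect_equal(max(segment_cells(matrix(100, 64, 64), cfg)), 0)

  sim <- synth_cell_image_pair(10, seed = 6, img_dim = c(300, 300),
                               radius_range = c(10, 16))
  labs <- segment_cells(sim$images$images$donor_before, cfg)
  expect_equal(max(labs), 10)

  # two overlapping disks with distinct centers split by the watershed
  img <- matrix(0, 120, 120)
  for (ctr in list(c(45, 60), c(75, 60))) {
    xr <- (ctr[1] - 18):(ctr[1] + 18)
    for (x in xr) for (y in (ctr[2] - 18):(ctr[2] + 18))
      if ((x - ctr[1])^2 + (y - ctr[2])^2 <= 18^2) img[x, y] <- 5000
  }
  labs2 <- segment_cells(img, cfg)
  expect_equal(max(labs2), 2)
})

test_that("region filters apply the area and circularity windows with audit", {
  cfg <- fret_config(pixel_size = 1)
  mk_disk <- function(dim, ctr, r) {
    im <- matrix(0L, dim, dim)
    for (x in 1:dim) for (y in 1:dim)
      if ((x - ctr[1])^2 + (y - ctr[2])^2 <= r^2) im[x, y] <- 1L
    im
  }
  # r=4: area ~50 um^2 (dropped), r=8: area ~201 um^2 (kept)
  labs <- mk_disk(80, c(20, 20), 4) + 2L * mk_disk(80, c(60, 60), 8)
  out <- filter_regions(labs, cfg)
  expect_equal(nrow(out$audit), 2)
  small <- out$audit[out$audit$label == 1, ]
  big <- out$audit[out$audit$label == 2, ]
  expect_false(small$kept); expect_equal(small$reason, "area")
  expect_true(big$kept)
  expect_gt(big$circularity, 0.8)

  # 1-px-wide snake of in-range area has circularity below 0.1
  snake <- matrix(0L, 140, 140)
  snake[10:110, 70] <- 1L   # 101 px = 101 um^2 at 1 um/px
  out2 <- filter_regions(snake, cfg)
  expect_false(out2$audit$kept)
  expect_equal(out2$audit$reason, "circularity")
  expect_lt(out2$audit$circularity, 0.1)

  # audit conservation: in = kept + dropped by reason
  expect_equal(nrow(out$audit),
               sum(out$audit$kept) + sum(out$audit$reason == "area") +
               sum(out$audit$reason == "circularity"))
})

test_that("correction factors are recovered from single-fluorophore controls", {
  set.seed(4)
  donor <- runif(40, 2000, 9000)
  donor_only <- data.frame(donor = donor, fret = 0.20 * donor + rnorm(40, sd = 20),
                           direct = rnorm(40, 50, 5))
  direct <- runif(40, 2000, 9000)
  acceptor_only <- data.frame(donor = rnorm(40, 50, 5),
                              fret = 0.0 * direct + rnorm(40, sd = 10),
                              direct = direct)
  f <- estimate_corrections(donor_only, acceptor_only)
  expect_equal(f$b, 0.20, tolerance = 0.01)
  expect_lt(abs(f$c), 0.005)

  expect_error(estimate_corrections(donor_only[1:5, ], acceptor_only),
               "at least 10")
  # contaminated controls trip the purity warning
  dirty <- donor_only; dirty$direct <- 0.5 * dirty$donor
  expect_warning(estimate_corrections(dirty, acceptor_only), "purity")
})

test_that("per-cell efficiencies, deltas and exclusion rules follow the caps", {
  cfg <- fret_config()
  f <- correction_factors(0.1, 0.05)
  mk <- function(donor, fret, direct, donor2 = donor, fret2 = fret,
                 direct2 = direct)
    data.frame(donor_before = donor, fret_before = fret,
               direct_before = direct, donor_after = donor2,
               fret_after = fret2, direct_after = direct2)
  # F_A = F_D after correction -> ef 0.5
  fd <- 3000; d <- 2000
  fret_raw <- fd + 0.1 * fd + 0.05 * d
  r <- compute_cell_fret(mk(fd, fret_raw, d), f, cfg)
  expect_equal(r$ef_before, 0.5)
  expect_false(r$excluded)
  expect_equal(r$delta_ef, r$ef_after - r$ef_before)

  # donor 12,000 -> over_bright
  r2 <- compute_cell_fret(mk(12000, 12000 * 1.1 + 100, 2000), f, cfg)
  expect_true(r2$over_bright)
  # direct change 2,500 -> direct_jump
  r3 <- compute_cell_fret(mk(fd, fret_raw, 2000, direct2 = 4500), f, cfg)
  expect_true(r3$direct_jump)
  # corrected ratio above 6 -> bad_ratio
  r4 <- compute_cell_fret(mk(7000, 0.1 * 7000 + 0.05 * 2000 + 7000 / 8, 2000),
                          f, cfg)
  expect_true(r4$bad_ratio)
  # efficiency is invariant to scaling all channels of a cell
  r5 <- compute_cell_fret(mk(2 * fd, 2 * fret_raw, 2 * d), f, cfg)
  expect_equal(r5$ef_before, r$ef_before, tolerance = 1e-12)
})

test_that("distribution summaries follow the linear-interpolation convention", {
  s <- summarize_distribution(rep(3.2, 10))
  expect_equal(s$median, 3.2)
  expect_equal(unname(s$central50), c(3.2, 3.2))
  expect_equal(unname(s$central95), c(3.2, 3.2))

  v <- as.numeric(1:100)
  sv <- summarize_distribution(v)
  expect_equal(sv$median, 50.5)
  expect_equal(unname(sv$central50), c(25.75, 75.25))
  # equivariance under shifts
  sv2 <- summarize_distribution(v + 7)
  expect_equal(sv2$median, sv$median + 7)
  expect_equal(unname(sv2$central50), unname(sv$central50) + 7)
  expect_error(summarize_distribution(numeric(0)), "no data")
})

test_that("localization comparison normalizes and tests exactly when small", {
  cl <- compare_localization(c(1, 2, 3), c(4, 5, 6), 1, 1)
  expect_equal(cl$p_value, 0.1)
  expect_equal(cl$method, "exact")
  # symmetry under group swap
  cl2 <- compare_localization(c(4, 5, 6), c(1, 2, 3), 1, 1)
  expect_equal(cl2$p_value, cl$p_value)
  # identical groups: p = 1
  cl3 <- compare_localization(c(1, 2, 3), c(1, 2, 3), 1, 1)
  expect_equal(cl3$p_value, 1)
  # normalization by the GS baseline median
  cl4 <- compare_localization(c(2, 4, 6), c(4, 5, 6), 2, 1)
  expect_equal(cl4$normalized_a, c(1, 2, 3))
  expect_error(compare_localization(c(1, 2, 3), c(4, 5, 6), 0, 1),
               "positive")
  expect_error(compare_localization(c(1, 2), c(4, 5, 6), 1, 1), "3 cells")
})

test_that("the end-to-end pipeline recovers planted efficiencies and flags", {
  cfg <- fret_config()
  f <- correction_factors(0.2, 0.1)
  sim <- synth_cell_image_pair(50, ef_mean = 0.3, ef_sd = 0.05,
                               delta_ef = 0.05, factors = f,
                               planted_artifacts = 3, config = cfg,
                               seed = 7, img_dim = c(512, 512),
                               noise_frac = 0.01, shift = c(3, -2),
                               rotation_deg = 0.5)
  out <- run_pipeline(sim$images, f, cfg)
  expect_equal(out$summary_delta$median, 0.05, tolerance = 0.01)
  # exactly the three planted artifact cells are flagged
  expect_equal(out$audit$cells_excluded, 3)
  expect_equal(out$audit$flagged_over_bright, 1)
  expect_equal(out$audit$flagged_direct_jump, 1)
  expect_equal(out$audit$flagged_bad_ratio, 1)
  # audit conservation through the particle filter
  expect_equal(out$audit$regions_segmented,
               out$audit$regions_kept + out$audit$dropped_area +
               out$audit$dropped_circularity)
  expect_equal(out$audit$regions_kept,
               out$audit$cells_used + out$audit$cells_excluded)

  # no mixing, no noise, no motion: per-cell ef equals the planted truth
  clean <- synth_cell_image_pair(8, factors = correction_factors(0, 0),
                                 delta_ef = 0.05, seed = 9,
                                 img_dim = c(300, 300),
                                 radius_range = c(10, 18), noise_frac = 0,
                                 shift = c(0, 0))
  outc <- run_pipeline(clean$images, correction_factors(0, 0), cfg)
  cells <- outc$cells
  # 16-bit quantization bounds the agreement; match distributions
  ef_sorted <- sort(cells$ef_before)
  truth_sorted <- sort(clean$truth$ef_before)
  expect_equal(ef_sorted, truth_sorted, tolerance = 1e-3)
  expect_equal(sort(cells$delta_ef), sort(clean$truth$delta_ef),
               tolerance = 1e-3)
})

test_that("delta recovery is unbiased across seeds at the default noise", {
  cfg <- fret_config()
  f <- correction_factors(0.15, 0.08)
  meds <- vapply(1:8, function(s) {
    sim <- synth_cell_image_pair(20, delta_ef = 0.05, factors = f,
                                 config = cfg, seed = s,
                                 img_dim = c(360, 360), noise_frac = 0.01,
                                 shift = c(2, -1))
    run_pipeline(sim$images, f, cfg)$summary_delta$median
  }, numeric(1))
  expect_lt(abs(mean(meds) - 0.05), 0.005)
})
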