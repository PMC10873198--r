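# --- geometry helpers ------------------------------------------------------

# Rigid warp with bilinear interpolation: output(x) = im(R_theta (x-c) + c + t).
# theta in degrees, t in pixels, c the image center.  Out-of-frame samples
# are 0.
warp_rigid <- function(im, theta_deg, t) {
  d <- dim(im)
  ctr <- (d + 1) / 2
  th <- theta_deg * pi / 180
  xi <- matrix(rep(seq_len(d[1]), d[2]), d[1])
  yi <- matrix(rep(seq_len(d[2]), each = d[1]), d[1])
  xs <- cos(th) * (xi - ctr[1]) - sin(th) * (yi - ctr[2]) + ctr[1] + t[1]
  ys <- sin(th) * (xi - ctr[1]) + cos(th) * (yi - ctr[2]) + ctr[2] + t[2]
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  pick <- function(ix, iy) {
    ok <- ix >= 1 & ix <= d[1] & iy >= 1 & iy <= d[2]
    v <- numeric(length(ix))
    v[ok] <- im[cbind(ix[ok], iy[ok])]
    v
  }
  v <- (1 - fx) * (1 - fy) * pick(x0, y0) + fx * (1 - fy) * pick(x0 + 1, y0) +
    (1 - fx) * fy * pick(x0, y0 + 1) + fx * fy * pick(x0 + 1, y0 + 1)
  matrix(v, d[1], d[2])
}

# FFT circular cross-correlation: best integer+subpixel t maximizing
# sum_x a(x+t) b(x), plus the normalized correlation at the peak
cc_translation <- function(a, b) {
  d <- dim(a)
  a0 <- a - mean(a); b0 <- b - mean(b)
  cc <- Re(stats::fft(stats::fft(a0) * Conj(stats::fft(b0)),
                      inverse = TRUE)) / length(a0)
  peak <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  signed <- function(k, n) if (k - 1 > n / 2) k - 1 - n else k - 1
  tx <- signed(peak[1], d[1]); ty <- signed(peak[2], d[2])
  # subpixel: parabolic interpolation along each axis through the peak
  sub <- function(idx, n, axis) {
    im1 <- ((idx - 2) %% n) + 1; ip1 <- (idx %% n) + 1
    y1 <- if (axis == 1) cc[im1, peak[2]] else cc[peak[1], im1]
    y2 <- cc[peak[1], peak[2]]
    y3 <- if (axis == 1) cc[ip1, peak[2]] else cc[peak[1], ip1]
    den <- y1 - 2 * y2 + y3
    if (abs(den) < 1e-300) 0 else 0.5 * (y1 - y3) / den
  }
  ncc <- max(cc) / (sqrt(sum(a0^2) * sum(b0^2)) + 1e-300)
  list(t = c(tx + sub(peak[1], d[1], 1), ty + sub(peak[2], d[2], 2)),
       ncc = ncc)
}

#' Rigid registration of the after-frames to the before-frames
#'
#' Estimates the rigid transform (rotation up to +/- 5 degrees by
#' golden-section search, translation by FFT cross-correlation with
#' subpixel parabolic peak interpolation) that best aligns the after donor
#' channel with the before donor channel, and applies it to all three after
#' channels.
#'
#' @param image_set A [cell_image_set()].
#' @param max_rotation Rotation search half-range in degrees.
#' @param min_ncc Registration fails below this normalized correlation.
#' @return The image set with aligned after-frames and a `transform`
#'   attribute: `shift` (pixels applied to the after content), `rotation`
#'   (degrees) and `ncc`.
#' @export
register_rigid <- function(image_set, max_rotation = 5, min_ncc = 0.15) {
  b <- image_set$images$donor_before
  a <- image_set$images$donor_after
  score <- function(theta) {
    cc_translation(if (theta == 0) a else warp_rigid(a, theta, c(0, 0)),
                   b)$ncc
  }
  opt <- stats::optimize(score, c(-max_rotation, max_rotation), maximum = TRUE,
                         tol = 0.02)
  theta <- if (opt$objective > score(0) + 1e-6) opt$maximum else 0
  rot <- if (theta == 0) a else warp_rigid(a, theta, c(0, 0))
  tr <- cc_translation(rot, b)
  if (tr$ncc < min_ncc)
    stop("registration failed: correlation peak below floor", call. = FALSE)
  out <- image_set
  for (ch in c("donor_after", "fret_after", "direct_after"))
    out$images[[ch]] <- warp_rigid(image_set$images[[ch]], theta, tr$t)
  attr(out, "transform") <- list(shift = -tr$t, rotation = -theta,
                                 ncc = tr$ncc)
  out
}

#' Segment cells on the donor channel
#'
#' Fixed two-sided intensity threshold (raw counts), 3x3 disc morphological
#' opening, then a distance-transform watershed to split touching cells,
#' yielding a label mask.
#'
#' @param donor_before Donor-channel image (integer-valued counts).
#' @param config An [fret_config()] supplying the threshold window.
#' @return An integer label matrix (0 = background).
#' @export
segment_cells <- function(donor_before, config = fret_config()) {
  mask <- donor_before >= config$seg_low & donor_before <= config$seg_high
  mask <- EBImage::opening(EBImage::Image(mask * 1),
                           EBImage::makeBrush(3, shape = "disc"))
  labels <- EBImage::watershed(EBImage::distmap(mask))
  matrix(as.integer(EBImage::imageData(labels)), nrow(donor_before))
}

region_metrics <- function(labels, pixel_size) {
  ids <- sort(setdiff(unique(as.vector(labels)), 0L))
  if (length(ids) == 0)
    return(data.frame(label = integer(0), area_px = integer(0),
                      area = numeric(0), circularity = numeric(0)))
  contours <- EBImage::ocontour(EBImage::Image(labels))
  per <- vapply(ids, function(id) {
    ct <- contours[[as.character(id)]]
    if (is.null(ct)) ct <- contours[[id]]
    p <- rbind(ct, ct[1, , drop = FALSE])
    sum(sqrt(rowSums(diff(p)^2)))
  }, numeric(1))
  area_px <- tabulate(labels[labels > 0], nbins = max(ids))[ids]
  area <- area_px * pixel_size^2
  # 4*pi*A/P^2 with contour-length perimeter; capped at the ideal disk value
  circ <- pmin(4 * pi * area_px / pmax(per, 1e-300)^2, 1)
  data.frame(label = ids, area_px = area_px, area = area, circularity = circ)
}

#' Filter segmented regions by area and circularity
#'
#' Keeps regions whose physical area and circularity `4 pi A / P^2`
#' (perimeter from the traced boundary contour) fall inside the configured
#' windows.  Every region appears in the audit with its metrics and the
#' keep/drop reason; dropped regions are removed from the returned mask.
#'
#' @param labels Label matrix from [segment_cells()].
#' @param config An [fret_config()] (area and circularity windows, pixel
#'   size).
#' @return A list with `labels` (filtered mask) and `audit` (data frame with
#'   `label`, `area`, `circularity`, `kept`, `reason`).
#' @export
filter_regions <- function(labels, config = fret_config()) {
  m <- region_metrics(labels, config$pixel_size)
  ar <- config$area_range; cr <- config$circularity_range
  reason <- rep("kept", nrow(m))
  reason[m$circularity < cr[1] | m$circularity > cr[2]] <- "circularity"
  reason[m$area < ar[1] | m$area > ar[2]] <- "area"
  m$kept <- reason == "kept"
  m$reason <- reason
  out <- labels
  out[!(out %in% m$label[m$kept])] <- 0L
  list(labels = out, audit = m)
}

#' Estimate bleedthrough and cross-excitation correction factors
#'
#' From single-fluorophore control cells: donor bleedthrough `b` is the
#' slope of a regression through the origin of the FRET-channel mean on the
#' donor-channel mean over donor-only cells; cross-excitation `c` is the
#' same slope of FRET-channel on direct-channel over acceptor-only cells.
#' A purity check warns when donor-only controls show appreciable direct
#' acceptor signal (or acceptor-only controls appreciable donor signal).
#'
#' @param donor_only,acceptor_only Data frames of per-cell channel means
#'   with columns `donor`, `fret`, `direct`; at least 10 cells each.
#' @param purity_tol Control contamination warning threshold (fraction of
#'   the control's own channel median).
#' @return A `correction_factors` list with `b` and `c`.
#' @export
estimate_corrections <- function(donor_only, acceptor_only,
                                 purity_tol = 0.05) {
  for (df in list(donor_only, acceptor_only))
    if (nrow(df) < 10)
      stop("need at least 10 control cells per fluorophore", call. = FALSE)
  if (stats::median(donor_only$direct) >
      purity_tol * stats::median(donor_only$donor))
    warning("donor-only controls show direct acceptor signal: purity check failed")
  if (stats::median(acceptor_only$donor) >
      purity_tol * stats::median(acceptor_only$direct))
    warning("acceptor-only controls show donor signal: purity check failed")
  b <- sum(donor_only$fret * donor_only$donor) / sum(donor_only$donor^2)
  cc <- sum(acceptor_only$fret * acceptor_only$direct) /
    sum(acceptor_only$direct^2)
  # regression noise can push a true-zero factor slightly negative
  correction_factors(max(b, 0), max(cc, 0))
}

#' Correction factor container
#' @param b Donor bleedthrough fraction into the FRET channel, in [0, 1).
#' @param c Acceptor cross-excitation fraction into the FRET channel.
#' @return A `correction_factors` list.
#' @export
correction_factors <- function(b, c) {
  if (b < 0 || b >= 1 || c < 0 || c >= 1)
    stop("correction factors must lie in [0, 1)", call. = FALSE)
  structure(list(b = b, c = c), class = "correction_factors")
}

#' Per-cell ratiometric FRET efficiencies with exclusion flags
#'
#' For each cell and timepoint the corrected donor and acceptor signals are
#' `F_D = donor mean` and `F_A = fret mean - b * donor mean - c * direct
#' mean`, giving `E_f = F_A / (F_D + F_A)` and
#' `delta_ef = ef_after - ef_before`.  Cells violating an exclusion rule are
#' flagged, never silently dropped: `over_bright` above the intensity cap,
#' `direct_jump` when the direct acceptor emission changes by more than the
#' cap (cells that moved or lifted off), `bad_ratio` when the corrected
#' donor/acceptor ratio is negative or above the cap, and `undefined` when
#' `F_D + F_A <= 0`.
#'
#' @param records Data frame of per-cell channel means with columns
#'   `donor_before`, `fret_before`, `direct_before`, `donor_after`,
#'   `fret_after`, `direct_after` (extra columns are carried through).
#' @param factors A [correction_factors()].
#' @param config An [fret_config()] (caps and filter options).
#' @return The records extended with `F_D_*`, `F_A_*`, `ef_before`,
#'   `ef_after`, `delta_ef`, logical flag columns and `excluded`.
#' @export
compute_cell_fret <- function(records, factors, config = fret_config()) {
  r <- records
  for (tp in c("before", "after")) {
    fd <- r[[paste0("donor_", tp)]]
    fa <- r[[paste0("fret_", tp)]] - factors$b * fd -
      factors$c * r[[paste0("direct_", tp)]]
    r[[paste0("F_D_", tp)]] <- fd
    r[[paste0("F_A_", tp)]] <- fa
    tot <- fd + fa
    ef <- ifelse(tot > 0, fa / tot, NA_real_)
    r[[paste0("ef_", tp)]] <- ef
  }
  r$delta_ef <- r$ef_after - r$ef_before
  bright_ch <- paste0(config$intensity_cap_channel, "_before")
  r$over_bright <- r[[bright_ch]] > config$intensity_cap
  r$direct_jump <- abs(r$direct_after - r$direct_before) >
    config$direct_change_cap
  ratio_bad <- function(tp) {
    ratio <- r[[paste0("F_D_", tp)]] / r[[paste0("F_A_", tp)]]
    ratio < 0 | ratio > config$ratio_cap
  }
  r$bad_ratio <- if (config$ratio_filter_timepoint == "both")
    ratio_bad("before") | ratio_bad("after") else ratio_bad("before")
  r$undefined <- !is.finite(r$ef_before) | !is.finite(r$ef_after)
  r$excluded <- r$over_bright | r$direct_jump | r$bad_ratio | r$undefined
  class(r) <- c("cell_records", "data.frame")
  r
}

#' Violin-style distribution summary
#'
#' Median with central 50 percent (25th--75th) and central 95 percent
#' (2.5th--97.5th) percentile intervals, linear-interpolation percentile
#' convention.
#'
#' @param values Numeric vector, length >= 1 (NAs removed).
#' @return A `violin_summary` list: `n`, `median`, `central50`, `central95`.
#' @export
summarize_distribution <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) == 0) stop("no data to summarize", call. = FALSE)
  qs <- stats::quantile(values, c(0.025, 0.25, 0.5, 0.75, 0.975), type = 7,
                        names = FALSE)
  structure(list(n = length(values), median = qs[3],
                 central50 = qs[c(2, 4)], central95 = qs[c(1, 5)]),
            class = "violin_summary")
}

#' @export
print.violin_summary <- function(x, ...) {
  cat(sprintf(
    "n = %d, median = %.4g, central 50%% [%.4g, %.4g], central 95%% [%.4g, %.4g]\n",
    x$n, x$median, x$central50[1], x$central50[2], x$central95[1],
    x$central95[2]))
  invisible(x)
}

#' Compare subcellular localizations after GS-baseline normalization
#'
#' Each compartment's per-cell efficiencies are divided by the median
#' efficiency of an equivalent GS linker in that compartment, then compared
#' with a two-sided Mann-Whitney (Wilcoxon rank-sum) test: exact null
#' enumeration when the pooled sample is small (<= 12) and tie-free,
#' otherwise the normal approximation with tie correction.
#'
#' @param values_a,values_b Per-cell efficiencies of the two compartments
#'   (n >= 3 each).
#' @param gs_baseline_a,gs_baseline_b GS-equivalent median efficiencies used
#'   for normalization; must be positive.
#' @return A list with `normalized_a`, `normalized_b`, `p_value`,
#'   `statistic` (the Mann-Whitney U for group a) and `method`.
#' @export
compare_localization <- function(values_a, values_b, gs_baseline_a,
                                 gs_baseline_b) {
  if (gs_baseline_a <= 0 || gs_baseline_b <= 0)
    stop("GS baselines must be positive", call. = FALSE)
  if (length(values_a) < 3 || length(values_b) < 3)
    stop("need at least 3 cells per group", call. = FALSE)
  na <- values_a / gs_baseline_a
  nb <- values_b / gs_baseline_b
  ties <- anyDuplicated(c(na, nb)) > 0
  exact <- (length(na) + length(nb)) <= 12 && !ties
  wt <- suppressWarnings(stats::wilcox.test(na, nb, exact = exact,
                                            correct = FALSE))
  list(normalized_a = na, normalized_b = nb, p_value = wt$p.value,
       statistic = unname(wt$statistic),
       method = if (exact) "exact" else "normal approximation")
}

#' Run the full live-cell ratiometric FRET pipeline
#'
#' Register the after-frames to the before-frames, segment on the donor
#' channel before perturbation, filter particles by area and circularity,
#' average each kept region in every channel at both timepoints (the
#' before-frame mask is frozen and reused on the registered after-frames),
#' apply spectral-mixing corrections and exclusion rules, and summarize the
#' efficiency distributions over unflagged cells.
#'
#' @param image_set A [cell_image_set()].
#' @param factors A [correction_factors()].
#' @param config An [fret_config()].
#' @return A list with `cells` (per-cell records, flags included),
#'   `summary_ef` and `summary_delta` ([summarize_distribution()] over
#'   unflagged cells), `audit` (stage-by-stage counts), `region_audit` and
#'   `transform`.
#' @export
run_pipeline <- function(image_set, factors, config = fret_config()) {
  reg <- register_rigid(image_set)
  labels <- segment_cells(reg$images$donor_before, config)
  filt <- filter_regions(labels, config)
  ids <- sort(setdiff(unique(as.vector(filt$labels)), 0L))
  if (length(ids) == 0) stop("no cells survive the particle filter", call. = FALSE)

  imgs <- reg$images
  if (config$subtract_background) {
    bg_mask <- filt$labels == 0L
    imgs <- lapply(imgs, function(im) im - stats::median(im[bg_mask]))
  }
  means <- vapply(ids, function(id) {
    sel <- filt$labels == id
    vapply(imgs, function(im) mean(im[sel]), numeric(1))
  }, numeric(6))
  recs <- as.data.frame(t(means))
  names(recs) <- names(imgs)
  names(recs) <- sub("^(donor|fret|direct)_", "\\1_", names(recs))
  recs <- cbind(label = ids,
                filt$audit[match(ids, filt$audit$label),
                           c("area", "circularity")],
                recs)
  rownames(recs) <- NULL
  cells <- compute_cell_fret(recs, factors, config)

  used <- !cells$excluded
  audit <- list(
    regions_segmented = nrow(filt$audit),
    dropped_area = sum(filt$audit$reason == "area"),
    dropped_circularity = sum(filt$audit$reason == "circularity"),
    regions_kept = sum(filt$audit$kept),
    flagged_over_bright = sum(cells$over_bright),
    flagged_direct_jump = sum(cells$direct_jump),
    flagged_bad_ratio = sum(cells$bad_ratio),
    flagged_undefined = sum(cells$undefined),
    cells_excluded = sum(!used),
    cells_used = sum(used))
  list(cells = cells,
       summary_ef = summarize_distribution(cells$ef_before[used]),
       summary_delta = summarize_distribution(cells$delta_ef[used]),
       audit = audit, region_audit = filt$audit,
       transform = attr(reg, "transform"))
}
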