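render_disks <- function(dim, cx, cy, r, value) {
  im <- matrix(0, dim[1], dim[2])
  for (k in seq_along(cx)) {
    xr <- max(1, floor(cx[k] - r[k])):min(dim[1], ceiling(cx[k] + r[k]))
    yr <- max(1, floor(cy[k] - r[k])):min(dim[2], ceiling(cy[k] + r[k]))
    dx <- outer(xr - cx[k], rep(1, length(yr)))
    dy <- outer(rep(1, length(xr)), yr - cy[k])
    inside <- dx^2 + dy^2 <= r[k]^2
    im[xr, yr] <- im[xr, yr] + value[k] * inside
  }
  im
}

#' Synthetic three-channel before/after cell image pair with known truth
#'
#' Renders non-overlapping disk-shaped cells with per-cell FRET efficiencies
#' drawn from a Gaussian, mixes in donor bleedthrough and acceptor
#' cross-excitation, applies a planted change `delta_ef` plus a small rigid
#' shift (and optional rotation up to 2 degrees) to the after-frame to
#' exercise registration, and plants `planted_artifacts` extra cells that
#' each violate exactly one exclusion rule (over-bright donor, direct
#' acceptor jump, extreme donor/acceptor ratio, cycled in that order).
#' Per-cell total brightness splits between donor and FRET channels as
#' `F_D = (1 - E) A` and `F_A = E A`, so with zero mixing and zero noise
#' the measured `F_A / (F_D + F_A)` equals the planted efficiency exactly.
#' Photon noise is Gaussian with sd proportional to signal (camera-like).
#'
#' @param n_cells Number of regular cells (>= 1).
#' @param ef_mean,ef_sd Gaussian distribution of the planted before
#'   efficiency (draws clamped to [0.18, 0.95] so regular cells never trip
#'   the ratio filter).
#' @param delta_ef Planted efficiency change applied to every regular cell.
#' @param factors A [correction_factors()] mixed into the FRET channel.
#' @param planted_artifacts Number of rule-violating cells to plant.
#' @param config An [fret_config()] (pixel size; thresholds define what the
#'   artifact cells must exceed).
#' @param seed Integer seed; identical seeds give identical images and
#'   truth.
#' @param img_dim Image dimensions in pixels.
#' @param radius_range Disk radius range in pixels; the default straddles
#'   the 65--845 square-micron area window at the default pixel size so the
#'   area filter is exercised in both directions.
#' @param brightness_range Total per-cell signal range (counts).
#' @param direct_scale Direct acceptor channel intensity as a fraction of
#'   total brightness.
#' @param noise_frac Gaussian noise sd as a fraction of each pixel's signal.
#' @param shift After-frame translation in pixels (content displacement).
#' @param rotation_deg After-frame rotation in degrees (<= 2 recommended).
#' @return A list: `images` (a [cell_image_set()]), `truth` (per-cell table
#'   with centers, radius, area, planted efficiencies and the violated
#'   rule), `factors`, `transform`.
#' @export
synth_cell_image_pair <- function(n_cells, ef_mean = 0.3, ef_sd = 0.05,
                                  delta_ef = 0,
                                  factors = correction_factors(0, 0),
                                  planted_artifacts = 0,
                                  config = fret_config(), seed = 1L,
                                  img_dim = c(300, 300),
                                  radius_range = c(6, 28),
                                  brightness_range = c(4000, 9000),
                                  direct_scale = 0.8, noise_frac = 0,
                                  shift = c(3, -2), rotation_deg = 0) {
  if (n_cells < 1) stop("n_cells must be >= 1", call. = FALSE)
  n_tot <- n_cells + planted_artifacts
  set.seed(seed)
  margin <- max(radius_range) + 8
  cx <- numeric(0); cy <- numeric(0); rr <- numeric(0)
  tries <- 0
  while (length(cx) < n_tot) {
    r <- stats::runif(1, radius_range[1], radius_range[2])
    # artifact cells get mid-range radii so they always pass the particle
    # filter and their planted rule violation is what flags them
    if (length(cx) >= n_cells) r <- mean(radius_range) * 0.75
    x <- stats::runif(1, margin, img_dim[1] - margin)
    y <- stats::runif(1, margin, img_dim[2] - margin)
    ok <- all(sqrt((cx - x)^2 + (cy - y)^2) > rr + r + 4)
    if (ok) { cx <- c(cx, x); cy <- c(cy, y); rr <- c(rr, r) }
    tries <- tries + 1
    if (tries > 200 * n_tot)
      stop("could not place cells without overlap; reduce n_cells", call. = FALSE)
  }

  ef1 <- pmin(pmax(stats::rnorm(n_tot, ef_mean, ef_sd), 0.18), 0.95)
  ef2 <- pmin(pmax(ef1 + delta_ef, 0.02), 0.98)
  A <- stats::runif(n_tot, brightness_range[1], brightness_range[2])
  D <- direct_scale * A
  D2 <- D
  violation <- rep("", n_tot)
  if (planted_artifacts > 0) {
    kinds <- rep(c("over_bright", "direct_jump", "bad_ratio"),
                 length.out = planted_artifacts)
    for (j in seq_len(planted_artifacts)) {
      i <- n_cells + j
      violation[i] <- kinds[j]
      if (kinds[j] == "over_bright") {
        ef1[i] <- ef_mean; ef2[i] <- ef_mean + delta_ef
        A[i] <- 1.5 * config$intensity_cap / (1 - ef1[i])
        D[i] <- D2[i] <- direct_scale * mean(brightness_range)
      } else if (kinds[j] == "direct_jump") {
        D2[i] <- D[i] + 1.5 * config$direct_change_cap
      } else {
        ef1[i] <- 0.5 / (1 + config$ratio_cap * 2)  # ratio ~ 2x the cap
        ef2[i] <- min(ef1[i] + delta_ef, 0.98)
      }
    }
  }

  fd1 <- (1 - ef1) * A; fa1 <- ef1 * A
  fd2 <- (1 - ef2) * A; fa2 <- ef2 * A

  th <- rotation_deg * pi / 180
  ctr <- (img_dim + 1) / 2
  cx2 <- cos(th) * (cx - ctr[1]) - sin(th) * (cy - ctr[2]) + ctr[1] + shift[1]
  cy2 <- sin(th) * (cx - ctr[1]) + cos(th) * (cy - ctr[2]) + ctr[2] + shift[2]

  mix <- function(fd, fa, d) list(
    donor = fd, fret = fa + factors$b * fd + factors$c * d, direct = d)
  ch1 <- mix(fd1, fa1, D); ch2 <- mix(fd2, fa2, D2)
  imgs <- list(
    donor_before = render_disks(img_dim, cx, cy, rr, ch1$donor),
    fret_before = render_disks(img_dim, cx, cy, rr, ch1$fret),
    direct_before = render_disks(img_dim, cx, cy, rr, ch1$direct),
    donor_after = render_disks(img_dim, cx2, cy2, rr, ch2$donor),
    fret_after = render_disks(img_dim, cx2, cy2, rr, ch2$fret),
    direct_after = render_disks(img_dim, cx2, cy2, rr, ch2$direct))
  if (noise_frac > 0)
    imgs <- lapply(imgs, function(im)
      im + stats::rnorm(length(im), sd = noise_frac * im))
  imgs <- lapply(imgs, function(im) round(pmin(pmax(im, 0), 65535)))

  truth <- data.frame(
    cell = seq_len(n_tot), cx = cx, cy = cy, radius = rr,
    area_um2 = pi * rr^2 * config$pixel_size^2,
    ef_before = ef1, ef_after = ef2, delta_ef = ef2 - ef1,
    brightness = A, violation = violation)
  list(images = cell_image_set(imgs, config$pixel_size), truth = truth,
       factors = factors,
       transform = list(shift = shift, rotation = rotation_deg))
}
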