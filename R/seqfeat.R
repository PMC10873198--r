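# Kyte-Doolittle hydropathy scale
KD_SCALE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
              E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
              M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
              Y = -1.3, V = 4.2)

split_seq <- function(sequence) {
  aa <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(aa, names(KD_SCALE))
  if (length(bad))
    stop("non-standard amino acids: ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  aa
}

# charge per residue: D/E -1, K/R +1, H neutral, termini uncharged
residue_charges <- function(aa) {
  ch <- integer(length(aa))
  ch[aa %in% c("D", "E")] <- -1L
  ch[aa %in% c("K", "R")] <- 1L
  ch
}

#' Charge fractions of a sequence
#'
#' FCR is the fraction of charged residues `(n+ + n-) / N`; NCPR the net
#' charge per residue `(n+ - n-) / N`.  Aspartate and glutamate count as
#' negative, lysine and arginine as positive, histidine as neutral.
#'
#' @param sequence Amino-acid string (standard 20-letter alphabet).
#' @return Named vector `c(fcr, ncpr)`.
#' @export
charge_fractions <- function(sequence) {
  ch <- residue_charges(split_seq(sequence))
  c(fcr = mean(ch != 0), ncpr = mean(ch))
}

#' Windowed Kyte-Doolittle hydropathy profile
#'
#' Per-residue mean of the Kyte-Doolittle value over a centered window of
#' `window` residues, truncated (not mirrored) at the termini: positions
#' near an end average over the residues available.
#'
#' @param sequence Amino-acid string.
#' @param window Odd window size (default 5, the five nearest residues).
#' @return Numeric vector, one value per residue.
#' @export
hydropathy_profile <- function(sequence, window = 5) {
  if (window %% 2 == 0) stop("window must be odd", call. = FALSE)
  v <- unname(KD_SCALE[split_seq(sequence)])
  h <- window %/% 2
  n <- length(v)
  vapply(seq_len(n), function(i)
    mean(v[max(1, i - h):min(n, i + h)]), numeric(1))
}

# mean squared deviation of windowed charge asymmetry from the global
# asymmetry, for blob size g
delta_g <- function(ch, g) {
  n <- length(ch)
  if (n < g) return(NA_real_)
  fp <- mean(ch > 0); fm <- mean(ch < 0)
  sig_global <- if (fp + fm > 0) (fp - fm)^2 / (fp + fm) else 0
  starts <- seq_len(n - g + 1)
  cp <- c(0, cumsum(ch > 0)); cm <- c(0, cumsum(ch < 0))
  wp <- (cp[starts + g] - cp[starts]) / g
  wm <- (cm[starts + g] - cm[starts]) / g
  tot <- wp + wm
  sig_w <- ifelse(tot > 0, (wp - wm)^2 / tot, 0)
  mean((sig_w - sig_global)^2)
}

# canonical maximally segregated arrangement of a composition: all
# positives contiguous, then the neutrals, then the negatives.  Its mirror
# image and charge-swapped image have identical delta (windowed asymmetry
# is reversal-invariant and squares the sign), so one arrangement defines
# the normalization; clamping in kappa absorbs the rare short-sequence
# permutations whose delta exceeds it
segregated_arrangement <- function(n_pos, n_neg, n_neu) {
  c(rep(1L, n_pos), rep(0L, n_neu), rep(-1L, n_neg))
}

kappa_for_charges <- function(ch, g_sizes = c(5, 6)) {
  n_pos <- sum(ch > 0); n_neg <- sum(ch < 0); n_neu <- sum(ch == 0)
  ratios <- vapply(g_sizes, function(g) {
    dg <- delta_g(ch, g)
    if (is.na(dg)) return(NA_real_)
    dmax <- delta_g(segregated_arrangement(n_pos, n_neg, n_neu), g)
    if (is.na(dmax) || dmax <= 0) return(NA_real_)
    dg / dmax
  }, numeric(1))
  ratios <- ratios[!is.na(ratios)]
  if (length(ratios) == 0) return(NA_real_)
  min(max(mean(ratios), 0), 1)
}

#' Charge-patterning parameter kappa
#'
#' The blob-based charge-patterning descriptor of disordered sequences:
#' for blob sizes 5 and 6, the local charge asymmetry
#' `sigma_w = (f+ - f-)^2 / (f+ + f-)` is computed over every sliding
#' window (windows without charges contribute 0), `delta` is the mean
#' squared deviation of `sigma_w` from the whole-sequence asymmetry, and
#' `delta_max` is the same quantity for the maximally charge-segregated
#' rearrangement of the same composition.  Kappa is the mean over the two
#' blob sizes of `delta / delta_max`, clamped to [0, 1]: near 1 when like
#' charges are clustered in blocks, small when they alternate.
#'
#' @param sequence Amino-acid string with at least one charged residue.
#' @return Kappa in [0, 1] (`NA` when undefined, e.g. no charge-asymmetry
#'   variation is possible for the composition).
#' @export
charge_kappa <- function(sequence) {
  ch <- residue_charges(split_seq(sequence))
  if (all(ch == 0))
    stop("kappa is undefined for sequences without charged residues",
         call. = FALSE)
  kappa_for_charges(ch)
}

#' All sequence descriptors at once
#'
#' @param sequence Amino-acid string.
#' @param window Hydropathy window (odd).
#' @return A `sequence_features` list: `sequence`, `fcr`, `ncpr`, `kappa`,
#'   `hydropathy_profile`.
#' @export
sequence_features <- function(sequence, window = 5) {
  cf <- charge_fractions(sequence)
  ch <- residue_charges(split_seq(sequence))
  kap <- if (any(ch != 0)) kappa_for_charges(ch) else NA_real_
  structure(list(sequence = sequence, fcr = unname(cf["fcr"]),
                 ncpr = unname(cf["ncpr"]), kappa = kap,
                 hydropathy_profile = hydropathy_profile(sequence, window)),
            class = "sequence_features")
}

#' @export
print.sequence_features <- function(x, ...) {
  cat(sprintf("sequence (%d aa): FCR = %.3f, NCPR = %+.3f, kappa = %s\n",
              nchar(x$sequence), x$fcr, x$ncpr,
              ifelse(is.na(x$kappa), "NA", sprintf("%.3f", x$kappa))))
  invisible(x)
}

#' Read sequences from FASTA or plain text
#'
#' @param path File path; FASTA when the first non-empty line starts with
#'   `>`, otherwise one sequence per line.
#' @return Named character vector of sequences.
#' @export
read_sequences <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (startsWith(trimws(lines[1]), ">")) {
    hdr <- grepl("^>", lines)
    id <- cumsum(hdr)
    seqs <- vapply(split(lines[!hdr], id[!hdr]),
                   function(x) paste(x, collapse = ""), character(1))
    names(seqs) <- sub("^>\\s*", "", lines[hdr])[as.integer(names(seqs))]
    seqs
  } else {
    stats::setNames(lines, paste0("seq", seq_along(lines)))
  }
}
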