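# shared fixtures: everything is generated in code, nothing is read from disk

default_cfg <- fret_config()
default_basis <- make_basis_spectra(default_cfg)

# all distinct permutations of a small multiset (oracle helper for kappa)
perms_multiset <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (u in unique(v)) {
    rest <- v[-match(u, v)]
    for (p in perms_multiset(rest)) out[[length(out) + 1L]] <- c(u, p)
  }
  unique(out)
}

# windowed charge-asymmetry deviation, re-derived independently (loop form)
# as the brute-force oracle for the vectorized implementation
delta_oracle <- function(ch, g) {
  n <- length(ch)
  if (n < g) return(NA_real_)
  fp <- sum(ch > 0) / n; fm <- sum(ch < 0) / n
  sig <- if (fp + fm > 0) (fp - fm)^2 / (fp + fm) else 0
  devs <- numeric(n - g + 1)
  for (i in seq_len(n - g + 1)) {
    w <- ch[i:(i + g - 1)]
    wp <- sum(w > 0) / g; wm <- sum(w < 0) / g
    sw <- if (wp + wm > 0) (wp - wm)^2 / (wp + wm) else 0
    devs[i] <- (sw - sig)^2
  }
  mean(devs)
}

# tiny dumbbell ensemble reused across ensemble tests
small_ensemble <- function(n = 24, s = 0, n_conf = 200, seed = 11) {
  sample_dumbbell_ensemble(dumbbell_params(
    n, s, n_conformers = n_conf, mc_steps = 200,
    equilibration_steps = 3000, seed = seed))
}
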