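# Small phantoms for fast unit tests; the full-size default spec is
# exercised in test-acceptance.R.

small_spec <- function(...) {
  phantom_spec(width = 20, height = 14, ...)
}

noiseless_spec <- function(...) {
  small_spec(noise_rel = 0, background_intensity = 0, ...)
}

# brute-force mass distribution of k monomers by enumeration over all 3^k
# label combinations, grouped by total mass
enumerate_monomers <- function(m, k) {
  combos <- expand.grid(rep(list(0:2), k))
  out <- numeric(2 * k + 1)
  for (i in seq_len(nrow(combos))) {
    lab <- as.integer(combos[i, ])
    out[sum(lab) + 1] <- out[sum(lab) + 1] + prod(m[lab + 1])
  }
  out
}

random_simplex <- function() {
  v <- stats::rexp(3)
  v / sum(v)
}
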