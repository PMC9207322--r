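# Independent oracles used across the suite.

# Brute-force orthonormal Haar basis for length n = 2^J: one column per
# basis function. Detail function (j, k) is +2^(-j/2) on the first half
# of its 2^j-sample support and -2^(-j/2) on the second half; the last
# column is the constant scaling function 2^(-J/2).
haar_basis_matrix <- function(n) {
  J <- as.integer(log2(n))
  stopifnot(2^J == n)
  cols <- list()
  for (j in seq_len(J)) {
    for (k in seq_len(n / 2^j)) {
      v <- numeric(n)
      s <- (k - 1) * 2^j
      v[s + seq_len(2^(j - 1))] <- 2^(-j / 2)
      v[s + 2^(j - 1) + seq_len(2^(j - 1))] <- -2^(-j / 2)
      cols[[length(cols) + 1L]] <- v
    }
  }
  cols[[length(cols) + 1L]] <- rep(2^(-J / 2), n)
  do.call(cbind, cols)
}

# Transform a signal by explicit inner products with the Haar basis,
# returned in the same structure as haar_dwt().
haar_oracle <- function(x) {
  n <- length(x)
  J <- as.integer(log2(n))
  B <- haar_basis_matrix(n)
  coefs <- drop(crossprod(B, x))
  details <- list()
  pos <- 0L
  for (j in seq_len(J)) {
    details[[j]] <- coefs[pos + seq_len(n / 2^j)]
    pos <- pos + n / 2^j
  }
  list(details = details, approx = coefs[length(coefs)])
}

# Relative effect P(X < Y) + 0.5 P(X = Y) by exhaustive enumeration.
enum_relative_effect <- function(x, y) {
  pairs_lt <- outer(x, y, "<")
  pairs_eq <- outer(x, y, "==")
  mean(pairs_lt + 0.5 * pairs_eq)
}

# Small deterministic noiseless recording for feature tests.
flat_recording <- function(value = 0, group = "control", id = "p1",
                           eye = "right", flash = 1.204) {
  ep <- epoch_grid()
  erg_recording(id, group, eye, flash,
                time_ms = ep$start_ms + (seq_len(ep$n_samples) - 1) * 1000 /
                  ep$sampling_rate_hz,
                amplitude_uv = rep(value, ep$n_samples))
}

# Tiny synthetic study used by I/O and pipeline tests.
small_study <- function(n_per_group = 3, flashes = 1.204, seed = 11,
                        groups = c("ASD", "control")) {
  sizes <- stats::setNames(rep(n_per_group, length(groups)), groups)
  spec <- cohort_spec(group_sizes = sizes, flash_strengths = flashes,
                      luminance_gain = rep(1, length(flashes)), seed = seed)
  generate_cohort(spec)
}
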