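# Shared helpers: small generators and independent oracles.

# Random track with n points at 5 s intervals
random_track <- function(n, id = "t1", spread = 20) {
  tibble::tibble(
    track_id = id,
    time_s = seq(0, by = 5, length.out = n),
    x_um = runif(n, -spread, spread),
    y_um = runif(n, -spread, spread)
  )
}

# O(n^2) brute-force maximum pairwise distance -- the oracle for
# max_excursion, kept independent of the implementation (no dist()).
brute_max_excursion <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  best <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
      if (d > best) best <- d
    }
  }
  best
}

# Straight-line track covering `excursion` um over `duration_s` seconds
straight_track <- function(excursion, duration_s = 300, dt = 5, id = "t1") {
  n <- duration_s / dt + 1
  tibble::tibble(
    track_id = id,
    time_s = seq(0, duration_s, by = dt),
    x_um = seq(0, excursion, length.out = n),
    y_um = 0
  )
}

# Noiseless processed Hertz curve for a known modulus
hertz_curve <- function(E_pa, R = 5.7, n = 50, delta_max = 2) {
  delta <- seq(delta_max / n, delta_max, length.out = n)
  tibble::tibble(delta_um = delta,
                 F_nN = (16 / 9) * sqrt(R) * (E_pa / 1000) * delta^1.5)
}
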