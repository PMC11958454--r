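# Small fixture builders shared across test files. Everything is generated
# in code; no binary fixtures.

# Noise-free config for photon-accounting tests.
quiet_config <- function(n_frames = 3L, shape = c(32L, 32L), ...) {
  sim_config(n_frames = n_frames, image_shape = shape,
             background_photons = 0, read_noise_sd = 0, bleach_prob = 0,
             rng_seed = 42L, ...)
}

# One immobile aggregate at a given position (um).
immobile_truth <- function(config, n_molecules, x_um, y_um) {
  simulate_aggregates(config, n_molecules, 0,
                      starts = matrix(c(x_um, y_um), 1))
}

# Label mask with a single full-frame cell.
one_cell <- function(shape) matrix(1L, shape[1], shape[2])

# Brute-force Mann-Whitney U statistic: pairwise wins with half-credit ties.
brute_force_u <- function(a, b) {
  sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
}

# Exact two-sided Mann-Whitney p by enumeration of all group assignments.
brute_force_u_pvalue <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a)
  obs <- brute_force_u(a, b)
  idx <- utils::combn(length(pooled), n)
  us <- apply(idx, 2, function(i) brute_force_u(pooled[i], pooled[-i]))
  mu <- length(a) * length(b) / 2
  mean(abs(us - mu) >= abs(obs - mu) - 1e-9)
}

# Noiseless photobleaching staircase trace.
staircase <- function(levels, dwell) rep(levels, each = dwell)
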