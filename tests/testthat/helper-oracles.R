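# Shared fixtures and independent brute-force oracles.
# Oracles deliberately avoid the package's FFT helpers: direct double sums.

tiny_config <- function(n = 8, pitch = 0.25, medium_index = 1.33, na = 1.25) {
  optical_config(pixel_pitch = pitch, nx = n, ny = n,
                 numerical_aperture = na, medium_index = medium_index)
}

random_complex_matrix <- function(n, seed) {
  set.seed(seed)
  matrix(complex(real = rnorm(n * n), imaginary = rnorm(n * n)), n, n)
}

# a random field with only in-band content (propagate by 0 applies cutoffs)
random_bandlimited_field <- function(config, seed) {
  propagate_field(complex_field(random_complex_matrix(config$nx, seed), config), 0)
}

# direct O(N^2) unitary 2D DFT, forward kernel exp(-j2pi k.r)
dft2_direct <- function(u) {
  ny <- nrow(u); nx <- ncol(u)
  out <- matrix(0 + 0i, ny, nx)
  for (ky in 0:(ny - 1)) for (kx in 0:(nx - 1)) {
    s <- 0 + 0i
    for (ry in 0:(ny - 1)) for (rx in 0:(nx - 1)) {
      s <- s + u[ry + 1, rx + 1] * exp(-2i * pi * (ky * ry / ny + kx * rx / nx))
    }
    out[ky + 1, kx + 1] <- s
  }
  out / sqrt(ny * nx)
}

# direct circular cross-correlation sum_m u(m) conj(h(m - r)), zero lag [1,1]
circ_corr2d_direct <- function(u, h) {
  ny <- nrow(u); nx <- ncol(u)
  out <- matrix(0 + 0i, ny, nx)
  for (ry in 0:(ny - 1)) for (rx in 0:(nx - 1)) {
    s <- 0 + 0i
    for (my in 0:(ny - 1)) for (mx in 0:(nx - 1)) {
      s <- s + u[my + 1, mx + 1] *
        Conj(h[((my - ry) %% ny) + 1, ((mx - rx) %% nx) + 1])
    }
    out[ry + 1, rx + 1] <- s
  }
  out
}

max_mod <- function(x) max(Mod(x))

rel_dev <- function(a, b) {
  pk <- max(max_mod(a), max_mod(b))
  if (pk == 0) 0 else max(Mod(a - b)) / pk
}

# support footprint above half maximum: small when in focus
focus_support <- function(field_values) {
  a <- Mod(field_values - mean(field_values))
  sum(a > max(a) / 2)
}

# memoized scaled training run shared by the acceptance tests
.acceptance_cache <- new.env(parent = emptyenv())

scaled_classifier <- function(seed = 7L) {
  key <- paste0("cl_", seed)
  if (is.null(.acceptance_cache[[key]])) {
    .acceptance_cache[[key]] <- train_rod_classifier(
      n_inclass = 6L, n_outclass = 6L, volume_shape = c(16L, 16L, 8L),
      rotations = 4L, kernel_extent = c(16L, 16L), seed = seed,
      schedule = anneal_schedule(seed = seed))
  }
  .acceptance_cache[[key]]
}
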