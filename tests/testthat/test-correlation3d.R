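# The plane-wise / 3D correlation equivalence and its building blocks.

test_that("an all-pass kernel at z = 0 returns the band-limited input", {
  cfg <- tiny_config(8)
  u <- random_bandlimited_field(cfg, 11)
  spec <- field_to_spectrum(u)
  ker <- spectral_kernel(matrix(1 + 0i, 8, 8), cfg)
  out <- correlate_plane(spec, ker, 0)
  expect_lt(rel_dev(out, u$values), 1e-10)
})

test_that("the matched-filter peak equals the template's in-band energy", {
  cfg <- tiny_config(16)
  u <- random_bandlimited_field(cfg, 12)
  spec <- field_to_spectrum(u)
  # kernel = spectrum of the template in the kernel (integral) convention,
  # i.e. the kernel whose impulse response is the template itself
  ker <- spectral_kernel(sqrt(length(u$values)) * spec$values, cfg)
  expect_lt(rel_dev(impulse_response_at(ker, 0), u$values), 1e-10)
  out <- correlate_plane(spec, ker, 0)
  expect_equal(Re(out[1, 1]), field_energy(u), tolerance = 1e-10)
  expect_equal(which.max(Mod(out)), 1L)      # peak at zero lag
})

test_that("correlation commutes with propagation", {
  cfg <- tiny_config(16)
  u <- random_bandlimited_field(cfg, 13)
  spec <- field_to_spectrum(u)
  ker <- spectral_kernel(random_complex_matrix(16, 14), cfg)
  z <- 2.3
  direct <- correlate_plane(spec, ker, z)
  # same correlation computed at z = 0, then propagated as a field to z
  at0 <- correlate_plane(spec, ker, 0)
  moved <- propagate_field(complex_field(at0, cfg, z = 0), z)
  expect_lt(rel_dev(direct, moved$values), 1e-10)
})

test_that("impulse responses reproduce correlate_plane as space-domain sums", {
  cfg <- tiny_config(16)
  u <- random_bandlimited_field(cfg, 15)
  spec <- field_to_spectrum(u)
  ker <- spectral_kernel(random_complex_matrix(16, 16), cfg)
  for (z in c(0, 1.5)) {
    h <- impulse_response_at(ker, z)
    ref <- circ_corr2d_direct(u$values, h)
    expect_lt(rel_dev(ref, correlate_plane(spec, ker, z)), 1e-10)
  }
  # z-dependence is a pure phase: energy independent of z
  e <- vapply(c(-3, 0, 2, 7), function(z) sum(Mod(impulse_response_at(ker, z))^2),
              numeric(1))
  expect_lt(diff(range(e)) / e[1], 1e-10)
  # all-pass kernel at z = 0: band-limited delta centred at the origin
  hd <- impulse_response_at(spectral_kernel(matrix(1 + 0i, 16, 16), cfg), 0)
  expect_equal(which.max(Mod(hd)), 1L)
})

test_that("correlate_volume equals the literal triple-sum oracle", {
  cfg <- tiny_config(8)
  u <- random_bandlimited_field(cfg, 17)
  vol <- reconstruct_volume(u, c(-1, -0.25, 0.5, 1.25))
  ker <- spectral_kernel(random_complex_matrix(8, 18), cfg)
  fast <- correlate_volume(vol, ker)
  slow <- brute_force_correlate3d(vol, ker)
  pk <- max(vapply(fast$planes, max_mod, numeric(1)))
  dev <- max(mapply(function(a, b) max(Mod(a - b)), fast$planes, slow$planes))
  expect_lt(dev / pk, 1e-10)
})

test_that("the oracle rejects big grids and maps a zero field to zero", {
  cfg <- tiny_config(8)
  ker <- spectral_kernel(matrix(1 + 0i, 8, 8), cfg)
  z <- c(0, 1)
  zero <- field_volume(lapply(z, function(zz)
    complex_field(matrix(0 + 0i, 8, 8), cfg, zz)), z)
  out <- brute_force_correlate3d(zero, ker)
  expect_true(all(vapply(out$planes, max_mod, numeric(1)) == 0))
  big <- tiny_config(32)
  ub <- random_bandlimited_field(big, 19)
  volb <- reconstruct_volume(ub, z)
  expect_error(brute_force_correlate3d(volb, spectral_kernel(matrix(1 + 0i, 32, 32), big)),
               "refused")
})

test_that("a point source is localized at its own position", {
  cfg <- tiny_config(16)
  src <- matrix(0 + 0i, 16, 16); src[6, 11] <- 1
  u <- propagate_field(complex_field(src, cfg), 0)
  spec <- field_to_spectrum(u)
  # template of a point at the origin: its correlation peaks at the source lag
  orig <- matrix(0 + 0i, 16, 16); orig[1, 1] <- 1
  ker <- spectral_kernel(field_to_spectrum(propagate_field(complex_field(orig, cfg), 0))$values,
                         cfg)
  out <- correlate_plane(spec, ker, 0)
  peak <- which(Mod(out) == max(Mod(out)), arr.ind = TRUE)
  expect_equal(unname(peak[1, ]), c(6, 11))
})

test_that("correlation is shift invariant, linear in u, conjugate-linear in H", {
  cfg <- tiny_config(8)
  u <- random_bandlimited_field(cfg, 20)
  ker <- spectral_kernel(random_complex_matrix(8, 21), cfg)
  out0 <- correlate_plane(field_to_spectrum(u), ker, 1.1)
  sh <- holofilter:::circshift2(u$values, 2, 5)
  outs <- correlate_plane(field_to_spectrum(complex_field(sh, cfg, u$z)), ker, 1.1)
  expect_lt(rel_dev(outs, holofilter:::circshift2(out0, 2, 5)), 1e-10)

  v <- random_bandlimited_field(cfg, 22)
  a <- 2.5 - 1i
  lhs <- correlate_plane(field_to_spectrum(
    complex_field(u$values + a * v$values, cfg)), ker, 0)
  rhs <- correlate_plane(field_to_spectrum(u), ker, 0) +
    a * correlate_plane(field_to_spectrum(v), ker, 0)
  expect_lt(rel_dev(lhs, rhs), 1e-10)

  ker2 <- spectral_kernel(a * ker$values, cfg)
  expect_lt(rel_dev(correlate_plane(field_to_spectrum(u), ker2, 0),
                    Conj(a) * correlate_plane(field_to_spectrum(u), ker, 0)), 1e-10)
})

test_that("config mismatches are refused", {
  cfg <- tiny_config(8); other <- tiny_config(8, pitch = 0.2)
  u <- random_bandlimited_field(cfg, 23)
  ker <- spectral_kernel(matrix(1 + 0i, 8, 8), other)
  expect_error(correlate_plane(field_to_spectrum(u), ker, 0), "do not match")
})
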