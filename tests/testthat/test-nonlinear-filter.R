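# The cascade: correlation layers, cubic thresholds, modulus, padding.

test_that("the threshold polynomial evaluates literally", {
  x <- array(c(2 + 0i, -1i, 0.5 + 0.5i, 0, 1, 2i, -3, 1 + 1i), c(2, 2, 2))
  expect_equal(apply_threshold(x, threshold_coeffs()), x)              # identity
  expect_equal(apply_threshold(x, threshold_coeffs(0, 0, 0, 4 - 1i)),
               array(4 - 1i, dim(x)))                                  # constant
  cc <- threshold_coeffs(1, 1, 1, 1)
  expect_equal(apply_threshold(array(2 + 0i, c(1, 1, 1)), cc),
               array(15 + 0i, c(1, 1, 1)))                             # 8+4+2+1
  expect_equal(apply_threshold(x, cc), x^3 + x^2 + x + 1)
})

test_that("the modulus operator returns elementwise intensity", {
  expect_equal(apply_modulus(array(1i, c(1, 1, 1))), array(1, c(1, 1, 1)))
  expect_equal(apply_modulus(array(3 + 4i, c(1, 1, 1))), array(25, c(1, 1, 1)))
  x <- array(complex(real = rnorm(8), imaginary = rnorm(8)), c(2, 2, 2))
  expect_true(all(apply_modulus(x) >= 0))
  expect_equal(apply_modulus(x), Mod(x)^2)
})

test_that("the correlation operator matches a literal per-plane sum on 4x4x2", {
  cfg <- tiny_config(4)
  u <- random_bandlimited_field(cfg, 31)
  vol <- reconstruct_volume(u, c(0, 0.5))
  ker <- spectral_kernel(random_complex_matrix(4, 32), cfg)
  out <- apply_correlation_op(vol, ker)
  # literal form: every plane 2D-circularly correlated with the fixed
  # space-domain kernel (modulo indexing on both axes)
  h <- impulse_response_at(ker, 0)
  for (m in 1:2) {
    ref <- circ_corr2d_direct(vol$planes[[m]]$values, h)
    expect_lt(rel_dev(out$planes[[m]], ref), 1e-12)
  }
})

test_that("a delta kernel is the band-limited identity on any volume", {
  cfg <- tiny_config(8)
  delta <- spectral_kernel(matrix(1 + 0i, 8, 8), cfg)
  u <- random_bandlimited_field(cfg, 33)
  vol <- reconstruct_volume(u, c(0, 1))
  out <- apply_correlation_op(vol, delta)
  expect_lt(rel_dev(out$planes[[1]], vol$planes[[1]]$values), 1e-10)
  # on a non-propagating (thresholded) volume it is the band-limited
  # identity: squaring creates out-of-band content, which is clipped
  cv <- apply_threshold(out, threshold_coeffs(b = 1, c = 0))
  out2 <- apply_correlation_op(cv, delta)
  bl <- holofilter:::fft2_unitary(cv$planes[[2]])
  bl[!band_mask(cfg)] <- 0
  expect_lt(rel_dev(out2$planes[[2]], holofilter:::ifft2_unitary(bl)), 1e-10)
})

test_that("the full cascade is circularly shift invariant", {
  cfg <- tiny_config(16)
  ker <- spectral_kernel(random_complex_matrix(16, 34), cfg)
  model <- filter_model(list(ker, spectral_kernel(matrix(1 + 0i, 16, 16), cfg)),
                        list(threshold_coeffs(a = 0.2, c = 1),
                             threshold_coeffs(a = 1, c = 0)),
                        kernel_extent = c(8, 8))
  u <- random_bandlimited_field(cfg, 35)
  zs <- c(0, 0.5, 1)
  out0 <- apply_filter(model, reconstruct_volume(u, zs))
  ush <- complex_field(holofilter:::circshift2(u$values, 3, -2), cfg)
  outs <- apply_filter(model, reconstruct_volume(ush, zs))
  for (m in seq_along(zs)) {
    expect_lt(rel_dev(outs$values[, , m],
                      holofilter:::circshift2(out0$values[, , m], 3, -2)), 1e-9)
  }
})

test_that("a two-layer model equals the manual composition of the three ops", {
  cfg <- tiny_config(8)
  k1 <- spectral_kernel(random_complex_matrix(8, 36), cfg)
  k2 <- spectral_kernel(random_complex_matrix(8, 37), cfg)
  t1 <- threshold_coeffs(a = 0.1, b = 0.3 + 0.1i)
  t2 <- threshold_coeffs(c = 2i, d = 0.5)
  model <- filter_model(list(k1, k2), list(t1, t2), kernel_extent = c(4, 4))
  u <- random_bandlimited_field(cfg, 38)
  vol <- reconstruct_volume(u, c(-0.5, 0, 0.5))
  auto <- apply_filter(model, vol)
  manual <- apply_modulus(
    apply_threshold(
      apply_correlation_op(
        apply_threshold(apply_correlation_op(vol, k1), t1), k2), t2))
  expect_lt(rel_dev(auto$values, manual$values), 1e-12)
})

test_that("with one linear layer the cascade reduces to |correlate_volume|^2", {
  cfg <- tiny_config(8)
  ker <- spectral_kernel(random_complex_matrix(8, 39), cfg)
  model <- filter_model(list(ker), kernel_extent = c(4, 4))
  u <- random_bandlimited_field(cfg, 40)
  vol <- reconstruct_volume(u, c(0, 0.7))
  out <- apply_filter(model, vol)
  ref <- correlate_volume(vol, ker)
  for (m in 1:2) expect_lt(rel_dev(out$values[, , m], Mod(ref$planes[[m]])^2), 1e-12)
  expect_true(all(out$values >= 0))
})

test_that("pad/unpad embed the trainable support reversibly", {
  cfg <- optical_config(pixel_pitch = 0.25, nx = 32, ny = 32)
  supp <- random_complex_matrix(16, 41)
  ker <- pad_kernel(supp, cfg)
  expect_lte(sum(ker$values != 0), 256)
  expect_identical(unpad_kernel(ker, c(16, 16)), supp)
  expect_error(pad_kernel(random_complex_matrix(64, 42), cfg), "larger")
  # padding a delta support reproduces the unpadded correlation
  d <- matrix(0 + 0i, 4, 4); d[3, 3] <- 1   # DC of a 4x4 centered block
  kp <- pad_kernel(d, cfg)
  u <- random_bandlimited_field(cfg, 43)
  spec <- field_to_spectrum(u)
  direct <- spectral_kernel({m <- matrix(0 + 0i, 32, 32); m[1, 1] <- 1; m}, cfg)
  expect_lt(rel_dev(correlate_plane(spec, kp, 0),
                    correlate_plane(spec, direct, 0)), 1e-12)
})

test_that("kernels transplanted to a larger grid preserve correlation peaks", {
  small <- optical_config(pixel_pitch = 0.25, nx = 16, ny = 16)
  big <- optical_config(pixel_pitch = 0.25, nx = 64, ny = 64)
  scene_s <- scene_placement(list(list(spec = rod_spec("in"), position = c(0, 0, 0))), small)
  u_s <- render_scene(scene_s)
  spec_s <- subtract_background(field_to_spectrum(u_s))
  # anchor the template at the zero-lag origin, as trained kernels are
  fg <- holofilter:::freq_grid(small)
  sxy <- floor(16 / 2) * 0.25
  spec_s$values <- spec_s$values * exp(2i * pi * (fg$kx + fg$ky) * sxy)
  ker <- spectral_kernel(spec_s$values, small)
  peak_s <- max(Mod(correlate_plane(spec_s, ker, 0)))
  ker_b <- resample_kernel(ker, big)
  scene_b <- scene_placement(list(list(spec = rod_spec("in"), position = c(3, -2, 0))), big)
  u_b <- render_scene(scene_b)
  out_b <- Mod(correlate_plane(subtract_background(field_to_spectrum(u_b)), ker_b, 0))
  expect_equal(max(out_b), peak_s, tolerance = 0.05)
  # and the peak sits on the rod: row 33 - 8, col 33 + 12
  am <- which(out_b == max(out_b), arr.ind = TRUE)[1, ]
  expect_equal(unname(am), c(25, 45))
  expect_error(resample_kernel(ker, optical_config(pixel_pitch = 0.2, nx = 64)),
               "pitch")
})

test_that("model construction and application validate their inputs", {
  cfg <- tiny_config(8)
  ker <- spectral_kernel(matrix(1 + 0i, 8, 8), cfg)
  expect_error(filter_model(list()), "length")
  expect_error(filter_model(list(ker), kernel_extent = c(16, 16)))
  model <- filter_model(list(ker), kernel_extent = c(4, 4))
  other <- random_bandlimited_field(tiny_config(8, pitch = 0.2), 44)
  expect_error(apply_filter(model, reconstruct_volume(other, c(0, 1))), "do not match")
})
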