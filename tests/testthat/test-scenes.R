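# Synthetic rods, scene composition, holograms, training-set generation.

test_that("rod rendering respects the capsule geometry", {
  cfg <- optical_config(pixel_pitch = 0.25, nx = 64, ny = 64)
  r0 <- render_rod(rod_spec("in", orientation = 0), cfg)
  r180 <- render_rod(rod_spec("in", orientation = 180), cfg)
  expect_lt(max(Mod(r0 - r180)), 1e-12)              # rod symmetry
  # 45-degree steps sweep distinct poses within the rod's 180-degree
  # symmetry period (so 0 and 180 coincide, 45/90/135 are new)
  imgs <- lapply(0:7 * 45, function(a)
    render_rod(rod_spec("in", orientation = a), cfg))
  for (i in 2:4) expect_gt(max(Mod(imgs[[i]] - imgs[[1]])), 1e-3)
  expect_lt(max(Mod(imgs[[5]] - imgs[[1]])), 1e-12)
  # support area close to the analytic capsule area
  spec <- rod_spec("in")
  cov <- holofilter:::rod_coverage(spec, cfg)
  area <- sum(cov) * cfg$pixel_pitch^2
  analytic <- (spec$length - spec$width) * spec$width + pi * (spec$width / 2)^2
  perimeter <- 2 * (spec$length - spec$width) + pi * spec$width
  expect_lt(abs(area - analytic), perimeter * cfg$pixel_pitch)
  # at 90 degrees the bounding box transposes
  c90 <- holofilter:::rod_coverage(rod_spec("in", orientation = 90), cfg)
  expect_lt(max(abs(c90 - t(cov))), 1e-12)
  expect_error(render_rod(rod_spec("in", length = 100, width = 1), cfg), "larger")
})

test_that("scene rendering composes single-scattered rods on a unit wave", {
  cfg <- optical_config(pixel_pitch = 0.25, nx = 64, ny = 64)
  empty <- render_scene(scene_placement(list(), cfg))
  expect_lt(max(Mod(empty$values - 1)), 1e-12)       # unit plane wave
  one <- scene_placement(list(list(spec = rod_spec("in"), position = c(0, 0, 0))), cfg)
  fld <- render_scene(one)
  obj <- render_rod(rod_spec("in"), cfg)
  # single rod at focus: its band-limited object function
  g <- holofilter:::fft2_unitary(obj - 1)
  g[!band_mask(cfg)] <- 0
  expect_lt(rel_dev(fld$values, 1 + holofilter:::ifft2_unitary(g)), 1e-10)
  expect_error(scene_placement(list(
    list(spec = rod_spec("in"), position = c(0, 0, 0)),
    list(spec = rod_spec("in"), position = c(0.5, 0, 0))), cfg), "overlap")
  expect_error(scene_placement(list(
    list(spec = rod_spec("in"), position = c(100, 0, 0))), cfg), "outside")
})

test_that("random scenes are reproducible and respect separations", {
  cfg <- optical_config(pixel_pitch = 0.25, nx = 128, ny = 128)
  s1 <- random_scene(4, 3, cfg, seed = 9)
  s2 <- random_scene(4, 3, cfg, seed = 9)
  expect_identical(lapply(s1$rods, `[[`, "position"),
                   lapply(s2$rods, `[[`, "position"))
  labs <- vapply(s1$rods, function(r) r$spec$class_label, character(1))
  expect_equal(sum(labs == "in"), 4L)
  # rendering a fixed placement twice is deterministic
  expect_identical(render_scene(s1)$values, render_scene(s1)$values)
})

test_that("off-axis holograms record and demodulate the field", {
  cfg <- optical_config(pixel_pitch = 0.1, nx = 64, ny = 64,
                        numerical_aperture = 0.4, medium_index = 1.33)
  carrier <- c(2.34375, 0.46875)  # on the spectral grid: exact sideband shift
  # zero field: uniform intensity r^2
  zero <- complex_field(matrix(0 + 0i, 64, 64), cfg)
  I0 <- simulate_hologram(zero, carrier, reference_amplitude = 1.5)
  expect_lt(max(abs(I0 - 2.25)), 1e-12)
  # uniform field: pure sinusoidal fringes at the carrier
  flat <- complex_field(matrix(1 + 0i, 64, 64), cfg)
  If <- simulate_hologram(flat, carrier)
  ph <- holofilter:::carrier_phase(cfg, carrier)
  expect_lt(max(abs(If - (2 + 2 * cos(ph)))), 1e-10)
  # round trip on a structured scene: exact within the NA band
  scene <- scene_placement(list(
    list(spec = rod_spec("in"), position = c(1.2, -0.8, 0.6)),
    list(spec = rod_spec("out"), position = c(-1.5, 1.0, -0.9))), cfg)
  u <- render_scene(scene)
  rec <- demodulate_hologram(simulate_hologram(u, carrier, 2), carrier, cfg, 2)
  expect_lt(rel_dev(rec$values, u$values), 1e-6)
  # degenerate inputs
  expect_lt(max(Mod(demodulate_hologram(matrix(0, 64, 64), carrier, cfg)$values)), 1e-12)
  carr_only <- demodulate_hologram(If, carrier, cfg)
  expect_lt(rel_dev(carr_only$values, flat$values), 1e-6)
  expect_error(simulate_hologram(u, c(0.5, 0)), "carrier")
  expect_error(simulate_hologram(u, c(100, 0)), "Nyquist")
  expect_error(demodulate_hologram(I0, c(0.1, 0), cfg), "overlaps")
})

test_that("training sets follow the rotation protocol and are reproducible", {
  ts <- build_training_set(rng_seed = 21)     # defaults: 25 + 17 references
  expect_equal(length(ts$references), 42L)
  expect_equal(sum(ts$labels == "in"), 25L)
  expect_equal(ts$meta$orientation_deg[1:9], c(0:7 * 45, 0))
  ts2 <- build_training_set(rng_seed = 21)
  expect_identical(ts$references[[5]]$planes[[2]]$values,
                   ts2$references[[5]]$planes[[2]]$values)
  sums <- vapply(seq_along(ts$desired), function(i) sum(ts$desired[[i]]), numeric(1))
  expect_true(all(sums[ts$labels == "in"] == 1))
  expect_true(all(sums[ts$labels == "out"] == 0))
  expect_error(build_training_set(2, 2, volume_shape = c(4, 4, 2),
                                  config = tiny_config(4)), "too small")
})
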