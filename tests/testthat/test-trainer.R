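# Desired outputs, the peak-weighted objective, and the annealer.

test_that("desired outputs are a unit delta (in-class) or zero (out-of-class)", {
  d_in <- desired_output_for("in", c(4, 4, 2))
  expect_equal(sum(d_in), 1)
  expect_equal(d_in[1, 1, 1], 1)
  expect_equal(sum(d_in != 0), 1L)       # 31 zeros and one 1
  d_out <- desired_output_for("out", c(4, 4, 2))
  expect_true(all(d_out == 0))
})

test_that("the objective matches its literal double-sum form", {
  # single reference, n = 4, all correct except the peak element off by 1:
  # E = 1 + 4 * 1 = 5
  O <- list(array(c(1, 0, 0, 0), c(2, 2, 1)))
  R <- list(array(c(0, 0, 0, 0), c(2, 2, 1)))
  expect_equal(objective(R, O), 5)
  # doubling the peak error quadruples its contribution
  R2 <- list(array(c(-1, 0, 0, 0), c(2, 2, 1)))
  expect_equal(objective(R2, O), 20)
  # random inputs against an independent double sum
  set.seed(50)
  shape <- c(3, 2, 2); n <- prod(shape); m <- 4
  R <- lapply(1:m, function(i) array(rnorm(n), shape))
  O <- lapply(1:m, function(i) array(rnorm(n), shape))
  E_ref <- 0
  for (j in 1:m) for (i in 1:n) E_ref <- E_ref + (R[[j]][i] - O[[j]][i])^2
  for (j in 1:m) E_ref <- E_ref + n * (R[[j]][1] - O[[j]][1])^2
  expect_equal(objective(R, O), E_ref, tolerance = 1e-12)
  expect_equal(objective(O, O), 0)
  expect_error(objective(list(array(0, c(2, 2, 1))), list(array(0, c(2, 2, 2)))),
               "mismatch")
})

test_that("a frozen schedule returns the initial model unchanged", {
  ts <- build_training_set(2, 0, volume_shape = c(12, 12, 2), rotations = 2,
                           rng_seed = 1, config = tiny_config(12), size_jitter = 0)
  mf <- matched_filter_kernel(ts, c(4, 4))
  m0 <- filter_model(list(mf), kernel_extent = c(4, 4))
  tr <- anneal(m0, ts, anneal_schedule(t_initial = 1, t_final = 1,
                                       steps_per_temperature = 0L))
  expect_identical(tr$model$kernels[[1]]$values, m0$kernels[[1]]$values)
  expect_equal(tr$final_E, tr$initial_E)
})

test_that("annealing is reproducible and its best trace never increases", {
  ts <- build_training_set(2, 2, volume_shape = c(12, 12, 4), rotations = 2,
                           rng_seed = 2, config = tiny_config(12), size_jitter = 0)
  mf <- matched_filter_kernel(ts, c(8, 8))
  m0 <- filter_model(list(mf), kernel_extent = c(8, 8))
  sched <- anneal_schedule(steps_per_temperature = 20L,
                           cooling_factor = 0.7, seed = 99L)
  tr1 <- anneal(m0, ts, sched)
  tr2 <- anneal(m0, ts, sched)
  expect_identical(tr1$model$kernels[[1]]$values, tr2$model$kernels[[1]]$values)
  expect_identical(tr1$trace$best_E, tr2$trace$best_E)
  expect_false(is.unsorted(rev(tr1$trace$best_E)))
  expect_lte(tr1$final_E, tr1$initial_E)
})

test_that("annealing a toy problem beats or matches the matched filter", {
  # 4x4x2 volume, one in-class reference, linear threshold fixed: the
  # annealer starts at the matched filter, so its error can only improve
  ts <- build_training_set(1, 0, volume_shape = c(4, 4, 2), rotations = 1,
                           rng_seed = 3, config = tiny_config(4),
                           size_jitter = 0, length = 0.7, width = 0.4)
  mf <- matched_filter_kernel(ts, c(4, 4))
  m0 <- filter_model(list(mf), kernel_extent = c(4, 4))
  E_matched <- objective(list(apply_filter(m0, ts$references[[1]])$values),
                         ts$desired)
  tr <- anneal(m0, ts, anneal_schedule(steps_per_temperature = 30L,
                                       cooling_factor = 0.8, seed = 4L))
  expect_lte(tr$final_E, E_matched * 1.1)
  expect_lt(tr$final_E, E_matched)   # it genuinely optimizes
})

test_that("evaluation statistics are consistent with apply_filter outputs", {
  ts <- build_training_set(2, 2, volume_shape = c(12, 12, 4), rotations = 2,
                           rng_seed = 5, config = tiny_config(12), size_jitter = 0)
  mf <- matched_filter_kernel(ts, c(8, 8))
  model <- filter_model(list(mf), kernel_extent = c(8, 8))
  ev <- evaluate_filter(model, ts)
  out3 <- apply_filter(model, ts$references[[3]])$values
  expect_equal(ev$stats$peak[3], out3[1, 1, 1])
  expect_equal(ev$stats$max_output[3], max(out3))
  expect_equal(ev$discrimination_ratio,
               min(ev$stats$peak[ts$labels == "in"]) /
                 max(ev$stats$max_output[ts$labels == "out"]))
  expect_gt(ev$discrimination_ratio, 1)  # usable classifier on references
})

test_that("a perfect model reports an infinite discrimination ratio", {
  # fabricate a training set whose out-of-class reference is exactly zero
  cfg <- tiny_config(12)
  zpl <- function(z) complex_field(matrix(0 + 0i, 12, 12), cfg, z)
  rod <- build_training_set(1, 0, volume_shape = c(12, 12, 2), rotations = 1,
                            rng_seed = 6, config = cfg, size_jitter = 0)
  zero_vol <- field_volume(list(zpl(0), zpl(0.5)), c(0, 0.5))
  ts <- training_set(c(rod$references, list(zero_vol)), c("in", "out"))
  mf <- matched_filter_kernel(ts, c(8, 8))
  ev <- evaluate_filter(filter_model(list(mf), kernel_extent = c(8, 8)), ts)
  expect_identical(ev$discrimination_ratio, Inf)
})

test_that("tidy and glance summarise a training run", {
  ts <- build_training_set(1, 1, volume_shape = c(12, 12, 2), rotations = 1,
                           rng_seed = 7, config = tiny_config(12), size_jitter = 0)
  mf <- matched_filter_kernel(ts, c(4, 4))
  tr <- anneal(filter_model(list(mf), kernel_extent = c(4, 4)), ts,
               anneal_schedule(steps_per_temperature = 5L, cooling_factor = 0.5))
  td <- generics::tidy(tr)
  expect_true(all(c("step", "temperature", "current_E", "best_E") %in% names(td)))
  expect_equal(nrow(td), tr$trace$step[length(tr$trace$step)])
  gl <- generics::glance(tr)
  expect_equal(gl$final_E, tr$final_E)
  expect_equal(gl$n_layers, 1L)
})
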