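test_that("zero displacement makes the two states coincide", {
  mdl <- make_two_state_model(length = 12, displacement = 0, seed = 1)
  st <- model_states(mdl)
  expect_equal(st[[1]], st[[2]])
})

test_that("both ground-truth states have exact virtual bond lengths", {
  mdl <- make_two_state_model(length = 20, seed = 2)
  for (s in model_states(mdl)) {
    bonds <- sqrt(rowSums(diff(s)^2))
    expect_lt(max(abs(bonds - 3.8)), 1e-6)
  }
})

test_that("displacements vanish outside the mobile segment", {
  mdl <- make_two_state_model(length = 24, seed = 3)
  d <- mdl$state_displacements[[2]]
  outside <- setdiff(seq_len(24), mdl$mobile_segment)
  expect_true(all(d[outside, ] == 0))
  expect_gt(max(sqrt(rowSums(d^2))), 3)  # the hinge actually moves
})

test_that("model construction validates its arguments", {
  expect_error(make_two_state_model(length = 4), ">= 8")
  expect_error(make_two_state_model(mobile_fraction = 0), "\\(0, 1\\]")
  expect_error(make_two_state_model(populations = c(0.7, 0.7)), "sum to 1")
  expect_error(make_two_state_model(displacement = -1), ">= 0")
})

test_that("sampled ensembles reproduce the requested noise level", {
  mdl <- make_two_state_model(length = 15, noise_sigma = 0.3, seed = 4)
  ens <- sample_ensemble(mdl, n_conformers = 200, seed = 4)
  expect_equal(dim(ens$xyz)[3], 400L)
  # per-coordinate deviations from the true state, pooled
  st <- model_states(mdl)
  dev <- c()
  for (m in seq_len(200)) for (s in 1:2)
    dev <- c(dev, as.vector(ens$xyz[, , (m - 1) * 2 + s] - st[[s]]))
  expect_lt(abs(sd(dev) - 0.3) / 0.3, 0.15)

  zero <- make_two_state_model(length = 15, noise_sigma = 0, seed = 4)
  ez <- sample_ensemble(zero, n_conformers = 3, seed = 1)
  expect_equal(ez$xyz[, , 1], model_states(zero)[[1]])
  expect_equal(ez$xyz[, , 2], model_states(zero)[[2]])
})

test_that("ground-truth restraints are satisfied exactly by the truth", {
  mdl <- make_two_state_model(length = 20, noise_sigma = 0, seed = 5)
  rs <- restraints_from_model(mdl, seed = 5)
  truth <- sample_ensemble(mdl, n_conformers = 1, seed = 1)
  tf <- target_function(truth, rs)
  expect_equal(tf$value, 0)
})

test_that("restraint generation honours fraction, corruption and pairing", {
  mdl <- make_two_state_model(length = 20, seed = 6)
  rs_full <- restraints_from_model(mdl, seed = 6)
  up <- rs_full$restraints[rs_full$restraints$type == "upper", ]
  lo <- rs_full$restraints[rs_full$restraints$type == "lower", ]
  expect_equal(nrow(up), nrow(lo))           # exact distances: paired limits
  expect_true(all(lo$bound < up$bound))

  rs_half <- restraints_from_model(mdl, fraction = 0.5, seed = 6)
  expect_equal(sum(rs_half$restraints$type == "upper"),
               round(0.5 * nrow(up)))

  rs_up <- restraints_from_model(mdl, lower_limits = FALSE, seed = 6)
  expect_true(all(rs_up$restraints$type == "upper"))

  corr <- restraints_from_model(mdl, corrupt = data.frame(index = 3,
                                                          scale = 0.7),
                                seed = 6)
  up_c <- corr$restraints[corr$restraints$type == "upper", ]
  lo_c <- corr$restraints[corr$restraints$type == "lower", ]
  expect_equal(up_c$bound[3], up$bound[3] * 0.7, tolerance = 1e-12)
  expect_equal(up_c$bound[-3], up$bound[-3], tolerance = 1e-12)
  # the paired lower limit moves with the misassigned distance
  expect_equal(lo_c$bound[3], max(0.7 * (up$bound[3] - 0.2), 1.0),
               tolerance = 1e-12)
  expect_error(restraints_from_model(mdl, corrupt = data.frame(index = 1e4,
                                                               scale = 0.7)),
               "out of range")
})

test_that("population-weighted truth averaging respects the populations", {
  mdl <- make_two_state_model(length = 20, seed = 7,
                              populations = c(0.9, 0.1))
  rs <- restraints_from_model(mdl, seed = 7)
  st <- model_states(mdl)
  dA <- as.matrix(dist(st[[1]])); dB <- as.matrix(dist(st[[2]]))
  up <- rs$restraints[rs$restraints$type == "upper", ]
  for (i in seq_len(min(20, nrow(up)))) {
    expected <- r6_average(c(dA[up$resid_a[i], up$resid_b[i]],
                             dB[up$resid_a[i], up$resid_b[i]]),
                           weights = c(0.9, 0.1)) + 0.1
    expect_equal(up$bound[i], expected, tolerance = 1e-9)
  }
})

test_that("the model is deterministic per seed and varies across seeds", {
  m1 <- make_two_state_model(length = 16, seed = 9)
  m2 <- make_two_state_model(length = 16, seed = 9)
  m3 <- make_two_state_model(length = 16, seed = 10)
  expect_identical(m1$base_coords, m2$base_coords)
  expect_identical(m1$state_displacements, m2$state_displacements)
  expect_false(identical(m1$base_coords, m3$base_coords))
})

test_that("backend calculations reach near-zero violations on clean truth", {
  mdl <- make_two_state_model(length = 16, seed = 11)
  rs <- restraints_from_model(mdl, seed = 11)
  cfg <- backend_config(n_states = 2L, n_conformers_calculated = 10L,
                        n_conformers_kept = 5L, n_steps = 400L, seed = 1L)
  ens <- calculate_ensemble(rs, 16, cfg)
  expect_lt(target_function(ens, rs)$normalized, 1e-2)
})
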