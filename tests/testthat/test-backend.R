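small_cfg <- function(...) {
  backend_config(n_conformers_calculated = 6L, n_conformers_kept = 4L,
                 n_steps = 300L, ...)
}
no_restraints <- function() restraint_set(upl(integer(0), integer(0),
                                              numeric(0)))

test_that("config invariants are enforced", {
  expect_error(backend_config(n_conformers_kept = 30,
                              n_conformers_calculated = 10), "exceeds")
  expect_error(backend_config(n_steps = 0), ">= 1")
  expect_error(backend_config(bundling_width = -1), "> 0")
})

test_that("grouping schemes must cover 1..N with two non-empty groups", {
  g <- grouping_scheme(1:3, 10)
  expect_equal(g$A, 1:3)
  expect_equal(g$B, 4:10)
  expect_error(grouping_scheme(integer(0), 10), "empty")
  expect_error(grouping_scheme(1:10, 10), "empty")
  expect_error(grouping_scheme(c(1, 11), 10), "1..10")
})

test_that("an unrestrained single-state chain relaxes to its bond length", {
  cfg <- small_cfg(n_states = 1L, seed = 3L)
  ens <- calculate_ensemble(no_restraints(), 12, cfg)
  for (m in seq_len(ens$n_conformers)) {
    x <- get_entity(ens, m, 1)$xyz
    bonds <- sqrt(rowSums(diff(x)^2))
    expect_lt(max(abs(bonds - 3.8)), 0.1)
  }
})

test_that("a satisfiable upper limit is satisfied to high precision", {
  cfg <- small_cfg(n_states = 1L, seed = 4L)
  rs <- restraint_set(upl(2, 11, 8.0))
  ens <- calculate_ensemble(rs, 12, cfg)
  tf <- target_function(ens, rs)
  expect_lt(tf$value, 1e-3)
})

test_that("contradictory restraints stay violated and are reported", {
  cfg <- small_cfg(n_states = 1L, seed = 5L)
  rs <- restraint_set(rbind(upl(2, 7, 3.0, "upper"),
                            upl(2, 7, 6.0, "lower")))
  ens <- calculate_ensemble(rs, 10, cfg)
  tf <- target_function(ens, rs)
  expect_gt(tf$value, 0)
  expect_setequal(unique(tf$violations$restraint), 1:2)
})

test_that("restraints on non-CA atoms are mapped to beads with relaxation", {
  cfg <- small_cfg(n_states = 1L, seed = 6L)
  rs <- restraint_set(upl(2, 9, 5.0, atom = "HB2"))
  ens <- calculate_ensemble(rs, 10, cfg)
  # effective bead bound is 5 + 2 * 1.5 = 8
  d <- sqrt(sum((get_entity(ens, 1, 1)$xyz[2, ] -
                 get_entity(ens, 1, 1)$xyz[9, ])^2))
  expect_lt(d, 8.2)
  expect_error(calculate_ensemble(restraint_set(upl(2, 40, 5)), 10, cfg),
               "outside the sequence")
})

test_that("rank_and_select keeps the lowest objectives in stable order", {
  coords <- lapply(1:3, function(k) random_fold(5, k))
  ens <- bead_ensemble(coords, n_states = 1L)
  sel <- rank_and_select(ens, c(3, 1, 2), keep = 2)
  expect_equal(sel$n_conformers, 2L)
  expect_equal(attr(sel, "objectives"), c(1, 2))
  expect_equal(sel$xyz[, , 1], coords[[2]])
  expect_equal(sel$xyz[, , 2], coords[[3]])
  ident <- rank_and_select(ens, c(3, 1, 2), keep = 3)
  expect_equal(ident$n_conformers, 3L)
  expect_error(rank_and_select(ens, c(3, 1, 2), keep = 4), "cannot keep")
  expect_error(rank_and_select(ens, c(1, 2), keep = 1), "3 conformers")
})

test_that("the backend is deterministic for a fixed seed", {
  mdl <- make_two_state_model(length = 12, seed = 21)
  rs <- restraints_from_model(mdl, seed = 21)
  cfg <- small_cfg(n_states = 2L, seed = 7L)
  e1 <- calculate_ensemble(rs, 12, cfg)
  e2 <- calculate_ensemble(rs, 12, cfg)
  expect_identical(e1$xyz, e2$xyz)
  expect_identical(attr(e1, "objectives"), attr(e2, "objectives"))
})

test_that("gradient-descent mode descends monotonically", {
  mdl <- make_two_state_model(length = 10, seed = 22)
  rs <- restraints_from_model(mdl, seed = 22)
  beads <- mscorval:::map_restraints_to_beads(rs, 10, 1.5)
  cfg <- backend_config(n_states = 2L, n_steps = 150L)
  W <- mscorval:::bundling_matrix(cfg, NULL)
  evalfun <- function(x)
    mscorval:::eval_objective(x, 10L, 2L, beads, cfg, W)
  set.seed(1)
  par <- rnorm(60, sd = 4)
  res <- mscorval:::gd_minimize(par, evalfun, 150)
  expect_true(all(diff(res$trace) <= 1e-12))
  expect_lt(res$value, evalfun(par)$energy)
})

test_that("analytic gradients match finite differences", {
  mdl <- make_two_state_model(length = 8, seed = 23)
  rs <- restraints_from_model(mdl, seed = 23)
  beads <- mscorval:::map_restraints_to_beads(rs, 8, 1.5)
  cfg <- backend_config(n_states = 2L)
  W <- mscorval:::bundling_matrix(cfg, NULL)
  evalfun <- function(x) mscorval:::eval_objective(x, 8L, 2L, beads, cfg, W)
  set.seed(2)
  x0 <- rnorm(48, sd = 3)
  g <- evalfun(x0)$gradient
  h <- 1e-6
  num <- vapply(seq_along(x0), function(i) {
    xp <- x0; xp[i] <- xp[i] + h
    xm <- x0; xm[i] <- xm[i] - h
    (evalfun(xp)$energy - evalfun(xm)$energy) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(g - num)), 1e-4 * max(1, max(abs(g))))
})

test_that("the backend expresses state splitting when the data demand it", {
  # noise-free two-state restraints: the two-state calculation must carry
  # more state separation than a one-state calculation of the same data
  # evaluated as a two-way split
  mdl <- make_two_state_model(length = 30, seed = 3)
  rs <- restraints_from_model(mdl, seed = 3)
  cfg2 <- backend_config(n_states = 2L, n_conformers_calculated = 16L,
                         n_conformers_kept = 10L, n_steps = 400L, seed = 1L)
  cfg1 <- backend_config(n_states = 1L, n_conformers_calculated = 16L,
                         n_conformers_kept = 10L, n_steps = 400L, seed = 1L)
  mu2 <- mscor(calculate_ensemble(rs, 30, cfg2), n_states = 2, seed = 0)$mu
  mu1 <- mscor(calculate_ensemble(rs, 30, cfg1), n_states = 2, seed = 0)$mu
  expect_gt(mu2, mu1)
})

test_that("assays accept a drop-in backend engine", {
  # an engine that ignores the restraints and returns a fixed rigid bundle
  canned <- function(restraints, sequence, config, grouping = NULL) {
    L <- if (length(sequence) == 1L) sequence else length(sequence)
    x <- random_fold(L, 77)
    coords <- rep(list(x), config$n_conformers_kept * config$n_states)
    bead_ensemble(coords, n_states = config$n_states)
  }
  rs <- restraint_set(upl(1, 5, 8))
  sc <- states_scan(rs, 10, backend_config(n_conformers_kept = 4L),
                    state_range = 1:2, seed = 1, engine = canned)
  expect_equal(nrow(sc), 2L)
  expect_equal(sc$mu[2], 0)  # rigid bundle carries no correlations
})

test_that("grouped bundling keeps in-group states together", {
  mdl <- make_two_state_model(length = 12, seed = 24)
  rs <- restraints_from_model(mdl, seed = 24)
  cfg <- backend_config(n_states = 4L, n_conformers_calculated = 4L,
                        n_conformers_kept = 2L, n_steps = 300L, seed = 8L)
  g <- grouping_scheme(1:2, 4)
  ens <- calculate_ensemble(rs, 12, cfg, grouping = g)
  for (m in seq_len(ens$n_conformers)) {
    s <- lapply(1:4, function(k) get_entity(ens, m, k)$xyz)
    within_a <- mean(sqrt(rowSums((s[[1]] - s[[2]])^2)))
    within_b <- mean(sqrt(rowSums((s[[3]] - s[[4]])^2)))
    expect_lt(within_a, 1.5)
    expect_lt(within_b, 1.5)
  }
})
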