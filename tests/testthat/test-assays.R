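# Assay semantics on deliberately small systems; the full-scale behaviour
# (state-count recovery, population recovery, titration monotonicity,
# corruption detection) is exercised in test-acceptance.R.

tiny_system <- function(seed = 31) {
  mdl <- make_two_state_model(length = 14, seed = seed)
  list(model = mdl, rs = restraints_from_model(mdl, seed = seed))
}
tiny_cfg <- function(...) {
  backend_config(n_conformers_calculated = 6L, n_conformers_kept = 4L,
                 n_steps = 200L, ...)
}

test_that("states_scan reports mu only for two or more states", {
  sys <- tiny_system()
  sc <- states_scan(sys$rs, 14, tiny_cfg(), state_range = 1:3, seed = 1)
  expect_s3_class(sc, "ms_scan")
  expect_equal(nrow(sc), 3L)
  expect_true(is.na(sc$mu[sc$n_states == 1]))
  expect_true(all(!is.na(sc$mu[sc$n_states >= 2])))
  expect_true(all(c("normalized_target_function", "ensemble_rmsd") %in%
                    names(sc)))
  expect_true(attr(sc, "optimum") %in% 2:3)
  expect_error(states_scan(sys$rs, 14, tiny_cfg(), state_range = 1),
               "at least 2")
})

test_that("population_scan builds two-representative bundles per group size", {
  sys <- tiny_system()
  ps <- population_scan(sys$rs, 14, tiny_cfg(), total_states = 4,
                        group_sizes = c(1, 2, 3), seed = 2)
  expect_equal(nrow(ps), 3L)
  expect_equal(ps$population_a, c(0.25, 0.5, 0.75))
  expect_true(all(!is.na(ps$mu)))
  expect_true(attr(ps, "optimum") %in% 1:3)
  expect_error(population_scan(sys$rs, 14, tiny_cfg(), total_states = 4,
                               group_sizes = 0), "1..3")
})

test_that("titration subsamples restraints freshly and summarizes", {
  sys <- tiny_system()
  tt <- titration(sys$rs, 14, tiny_cfg(), fractions = c(0.5, 1),
                  replicates = 2, seed = 3)
  expect_equal(nrow(tt), 4L)
  n_up <- n_restraints(sys$rs)
  expect_true(all(tt$n_restraints[tt$fraction == 1] == n_up))
  expect_true(all(tt$n_restraints[tt$fraction == 0.5] == round(0.5 * n_up)))
  smry <- attr(tt, "summary")
  expect_true(all(c("mu", "mu_sd", "ensemble_rmsd_sd") %in% names(smry)))
  # fresh subsample per replicate: different replicate seeds may select
  # different restraints, but the same call is reproducible
  tt2 <- titration(sys$rs, 14, tiny_cfg(), fractions = c(0.5, 1),
                   replicates = 2, seed = 3)
  expect_identical(as.data.frame(tt), as.data.frame(tt2))
  expect_error(titration(sys$rs, 14, tiny_cfg(), fractions = 1.2),
               "\\(0, 1\\]")
  expect_warning(titration(sys$rs, 14, tiny_cfg(),
                           fractions = c(0.001, 1), replicates = 1,
                           seed = 1),
                 "skipped")
})

test_that("loo_ranking returns a disjoint total ordering with baseline", {
  sys <- tiny_system()
  rk <- loo_ranking(sys$rs, 14, tiny_cfg(), long_range_only = FALSE,
                    set_size = 3, seed = 4)
  up_idx <- which(sys$rs$restraints$type == "upper")
  expect_setequal(rk$restraint, up_idx)
  expect_equal(rk$rank, seq_len(nrow(rk)))
  expect_true(all(diff(rk$mu_without) >= 0))
  expect_length(intersect(attr(rk, "top_set"), attr(rk, "bottom_set")), 0)
  expect_length(attr(rk, "bottom_set"), 3L)
  expect_true(is.numeric(attr(rk, "baseline_mu")))
  # scope covering every upper restraint with set_size = count keeps the
  # sets disjoint by construction
  rk_all <- loo_ranking(sys$rs, 14, tiny_cfg(), long_range_only = FALSE,
                        set_size = length(up_idx), seed = 4)
  expect_length(intersect(attr(rk_all, "top_set"),
                          attr(rk_all, "bottom_set")), 0)
  expect_error(loo_ranking(sys$rs, 14, tiny_cfg(), min_separation = 100),
               "fewer than 2")
})

test_that("distance_profile bins pairs by distance with equal counts", {
  ens <- rigid_two_state_ensemble(M = 6, L = 8, seed = 13)
  # uniform synthetic matrix: every bin must average to the constant
  cm <- structure(list(A = matrix(0.42, 8, 8),
                       clusterings = vector("list", 8),
                       degenerate = rep(FALSE, 8), residues = 1:8,
                       n_states = 2L, threshold = 0.5),
                  class = "ms_cormat")
  pr <- distance_profile(ens, cm, n_bins = 4)
  expect_equal(nrow(pr), 4L)
  expect_equal(sum(pr$n_pairs), choose(8, 2))
  expect_true(all(abs(pr$mean_correlation - 0.42) < 1e-12))
  expect_true(all(diff(pr$mean_distance) > 0))
  # 28 pairs into 4 bins: equal counts of 7
  expect_equal(pr$n_pairs, rep(7L, 4))
  expect_error(distance_profile(ens, cm, n_bins = 29), "fewer residue pairs")
  expect_error(distance_profile(ens, cm, n_bins = 1), ">= 2")
})

test_that("near-range correlations exceed far-range ones for hinge motion", {
  # hinge-localized motion: residues near the mobile segment correlate,
  # distant pairs do not
  mdl <- make_two_state_model(length = 20, seed = 14)
  ens <- sample_ensemble(mdl, n_conformers = 15, seed = 14)
  fit <- mscor(ens, n_states = 2, seed = 0)
  pr <- distance_profile(ens, fit, n_bins = 5)
  expect_gt(pr$mean_correlation[1], pr$mean_correlation[5])
})

test_that("convergence_scan flags the cheapest converged cell", {
  sys <- tiny_system()
  sc <- convergence_scan(sys$rs, 14, tiny_cfg(), step_counts = c(20, 200),
                         conformer_counts = c(4, 6), seed = 5)
  expect_equal(nrow(sc), 4L)
  ref <- sc$mu[sc$n_steps == 200 & sc$n_conformers == 6]
  expect_equal(attr(sc, "reference_mu"), ref)
  expect_true(sc$converged[sc$n_steps == 200 & sc$n_conformers == 6])
  rec <- attr(sc, "recommended")
  expect_true(all(c("n_steps", "n_conformers") %in% names(rec)))
  # single cell is trivially converged
  one <- convergence_scan(sys$rs, 14, tiny_cfg(), step_counts = 50,
                          conformer_counts = 4, seed = 5)
  expect_true(one$converged)
})

test_that("compare_with_without toggles exactly one restraint", {
  sys <- tiny_system()
  cp <- compare_with_without(sys$rs, 1, 14, tiny_cfg(), seed = 6)
  expect_equal(rownames(cp), c("with", "without"))
  expect_true(all(is.finite(cp$mu)))
  expect_error(compare_with_without(sys$rs, 10000, 14, tiny_cfg()),
               "not found")
})

test_that("scan and ranking plot methods produce output", {
  sys <- tiny_system()
  sc <- states_scan(sys$rs, 14, tiny_cfg(), state_range = 1:2, seed = 7)
  rk <- loo_ranking(sys$rs, 14, tiny_cfg(), long_range_only = FALSE,
                    set_size = 2, seed = 7)
  f <- tempfile(fileext = ".png")
  grDevices::png(f)
  expect_silent(plot(sc))
  expect_silent(plot(rk))
  grDevices::dev.off()
  expect_true(file.exists(f))
})
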