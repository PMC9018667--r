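test_that("CYANA-style restraint files parse correctly", {
  f <- tempfile(fileext = ".upl")
  writeLines(c("# eNOE-derived upper limits",
               "11 TRP H 26 ASN HB2 3.85",
               "",
               " 2 ALA CA 9 GLY CA 5.50  # trailing comment"), f)
  rs <- read_restraints(f, type = "upper")
  expect_equal(n_restraints(rs), 2L)
  r1 <- rs$restraints[1, ]
  expect_equal(r1$resid_a, 11L)
  expect_equal(r1$resname_a, "TRP")
  expect_equal(r1$atom_a, "H")
  expect_equal(r1$resid_b, 26L)
  expect_equal(r1$atom_b, "HB2")
  expect_equal(r1$bound, 3.85)
  expect_equal(r1$type, "upper")

  writeLines(character(0), f)
  expect_equal(n_restraints(read_restraints(f)), 0L)

  writeLines("11 TRP H 26 ASN 3.85", f)
  expect_error(read_restraints(f), "line 1.*7 fields")
  writeLines("11 TRP H 26 ASN HB2 -1.0", f)
  expect_error(read_restraints(f), "positive")
})

test_that("restraint files round-trip through write_restraints", {
  df <- rbind(upl(1, 5, 4.5), upl(2, 9, 6.25), upl(3, 8, 5.0, "lower"))
  rs <- restraint_set(df)
  f <- tempfile(fileext = ".upl")
  write_restraints(rs, f, type = "upper")
  back <- read_restraints(f, type = "upper")
  expect_equal(back$restraints$bound, c(4.5, 6.25))
  expect_equal(back$restraints$resid_b, c(5L, 9L))
})

test_that("r^-6 averaging obeys its identities, bounds and monotonicity", {
  expect_equal(r6_average(c(3, 3)), 3)
  expect_equal(r6_average(7.2), 7.2)

  # direct high-precision evaluation of the averaging formula
  d <- c(2.5, 10)
  ref <- ((2.5^-6 + 10^-6) / 2)^(-1 / 6)
  expect_equal(r6_average(d), ref, tolerance = 1e-12)
  expect_gte(r6_average(d), 2.5)
  expect_lte(r6_average(d), 2.5 * 2^(1 / 6))

  set.seed(1)
  for (i in 1:200) {
    n <- sample(1:6, 1)
    d <- runif(n, 0.5, 12)
    v <- r6_average(d)
    expect_gte(v, min(d) - 1e-12)
    expect_lte(v, min(d) * n^(1 / 6) + 1e-12)
    # permutation invariance
    expect_equal(r6_average(d[sample.int(length(d))]), v,
                 tolerance = 1e-12)
    # monotone non-decreasing in each argument
    j <- sample(n, 1)
    d2 <- d; d2[j] <- d2[j] + runif(1, 0, 3)
    expect_gte(r6_average(d2), v - 1e-12)
  }
  expect_error(r6_average(c(1, -2)), "positive")
  expect_error(r6_average(numeric(0)), "at least one")
})

test_that("population-weighted averaging reduces to the equal-weight form", {
  set.seed(2)
  for (i in 1:50) {
    d <- runif(3, 1, 10)
    expect_lt(abs(r6_average(d, weights = rep(1 / 3, 3)) - r6_average(d)),
              1e-12)
  }
  # weights shift the average toward the favoured state
  expect_lt(r6_average(c(3, 8), weights = c(0.9, 0.1)),
            r6_average(c(3, 8), weights = c(0.1, 0.9)))
})

test_that("the target function matches a brute-force loop on random cases", {
  set.seed(3)
  for (case in 1:100) {
    L <- 4; M <- 2; N <- 2
    coords <- lapply(seq_len(M * N), function(k)
      matrix(rnorm(3 * L, sd = 4), L, 3))
    ens <- bead_ensemble(coords, n_states = N)
    nR <- 5
    df <- upl(sample(L, nR, TRUE), sample(L, nR, TRUE),
              runif(nR, 2, 9),
              sample(c("upper", "lower", "steric"), nR, TRUE))
    keep <- df$resid_a != df$resid_b
    if (!any(keep)) next
    df <- df[keep, , drop = FALSE]
    w <- c(upper = 1, lower = 0.7, steric = 1.3)
    rs <- restraint_set(df, weights = w)
    got <- target_function(ens, rs)

    # independent loop: per conformer, per restraint, r^-6 state average
    per_conf <- numeric(M)
    for (m in seq_len(M)) {
      tot <- 0
      for (i in seq_len(nrow(df))) {
        ds <- vapply(seq_len(N), function(s) {
          xa <- coords[[(m - 1) * N + s]][df$resid_a[i], ]
          xb <- coords[[(m - 1) * N + s]][df$resid_b[i], ]
          sqrt(sum((xa - xb)^2))
        }, numeric(1))
        dstar <- (mean(ds^-6))^(-1 / 6)
        viol <- if (df$type[i] == "upper") dstar - df$bound[i]
                else df$bound[i] - dstar
        if (viol > 0) tot <- tot + w[[df$type[i]]] * viol^2
      }
      per_conf[m] <- tot
    }
    expect_equal(got$per_conformer, per_conf, tolerance = 1e-12)
    expect_equal(got$value, mean(per_conf), tolerance = 1e-12)
    expect_equal(got$normalized, mean(per_conf) / nrow(df),
                 tolerance = 1e-12)
  }
})

test_that("target function basics: empty set, single violation, reporting", {
  ens <- bead_ensemble(list(rbind(c(0, 0, 0), c(5, 0, 0))))
  empty <- restraint_set(upl(integer(0), integer(0), numeric(0)))
  expect_equal(target_function(ens, empty)$value, 0)
  expect_equal(nrow(target_function(ens, empty)$violations), 0L)

  rs <- restraint_set(upl(1, 2, 4.0))
  rep1 <- target_function(ens, rs)
  expect_equal(rep1$value, 1.0)   # (5 - 4)^2
  expect_equal(nrow(rep1$violations), 1L)
  expect_equal(rep1$violations$violation, 1.0)

  # value 0 iff no violations
  rs_ok <- restraint_set(upl(1, 2, 6.0))
  rep2 <- target_function(ens, rs_ok)
  expect_equal(rep2$value, 0)
  expect_equal(nrow(rep2$violations), 0L)
})

test_that("raising an upper bound never increases the target function", {
  set.seed(4)
  coords <- lapply(1:4, function(k) matrix(rnorm(15, sd = 4), 5, 3))
  ens <- bead_ensemble(coords, n_states = 2L)
  vals <- vapply(seq(3, 10, by = 0.5), function(b)
    target_function(ens, restraint_set(upl(1, 4, b)))$value, numeric(1))
  expect_true(all(diff(vals) <= 1e-12))
})

test_that("missing restrained atoms give a structured error", {
  ens <- bead_ensemble(list(rbind(c(0, 0, 0), c(5, 0, 0))))
  rs <- restraint_set(upl(1, 2, 4.0, atom = "HB2"))
  expect_error(target_function(ens, rs), "HB2 of residue 1")
})

test_that("violations report writes a readable TSV", {
  ens <- bead_ensemble(list(rbind(c(0, 0, 0), c(5, 0, 0))))
  rep1 <- target_function(ens, restraint_set(upl(1, 2, 4.0)))
  f <- tempfile(fileext = ".tsv")
  write_violations(rep1, f)
  back <- read.delim(f)
  expect_equal(nrow(back), 1L)
  expect_equal(back$violation, 1.0)
})
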