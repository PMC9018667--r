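# Validation assays: each runs the structure-calculation backend over a set
# of conditions, evaluates every bundle with the target function and the
# correlation engine, and returns a tidy per-condition table with the
# optimum or ranking attached as attributes.  All assays are deterministic
# given (restraints, config, seed).

mu_of <- function(ensemble, n_states, seed, threshold = 0.5, restarts = 10L) {
  mscor(ensemble, n_states = n_states, threshold = threshold, seed = seed,
        restarts = restarts)$mu
}

scan_result <- function(rows, summary, type, ...) {
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  structure(df, class = c("ms_scan", "data.frame"),
            summary = summary, scan_type = type, ...)
}

#' @export
print.ms_scan <- function(x, ...) {
  cat(sprintf("Scan (%s): %d rows\n", attr(x, "scan_type"), nrow(x)))
  print.data.frame(attr(x, "summary"), digits = 4)
  opt <- attr(x, "optimum")
  if (!is.null(opt)) cat("optimum:", opt, "\n")
  invisible(x)
}

#' State-number scan
#'
#' Recalculates the bundle with 1 to `S` states and evaluates each state
#' count with the normalized target function and (for two or more states)
#' the structural correlation mu computed with as many clusters as states.
#' The correlation shows a maximum at the true number of states, while the
#' target function merely levels off beyond it.
#'
#' @param restraints an `ms_restraints` set.
#' @param sequence residue names or an integer length (see
#'   [calculate_ensemble()]).
#' @param config an [backend_config()]; its `n_states` is overridden by the
#'   scanned condition.
#' @param state_range state counts to scan (default `1:9`).
#' @param replicates independent backend replicates per condition.
#' @param seed master seed; every condition and replicate derives its own.
#' @param threshold,restarts correlation-engine settings.
#' @param engine backend callable with the signature
#'   `function(restraints, sequence, config, grouping = NULL)` returning an
#'   [ms_ensemble()]; defaults to the built-in [calculate_ensemble()].  Any
#'   drop-in replacement (e.g. an adapter around an external
#'   structure-calculation program) can be supplied here.
#' @return an `ms_scan` data.frame with columns `n_states`, `replicate`,
#'   `target_function`, `normalized_target_function`, `mu`,
#'   `ensemble_rmsd`; attributes `summary` (per-condition means and sds)
#'   and `optimum` (state count maximizing mean mu).
#' @export
states_scan <- function(restraints, sequence, config = backend_config(),
                        state_range = 1:9, replicates = 1L, seed = 0L,
                        threshold = 0.5, restarts = 10L,
                        engine = calculate_ensemble) {
  if (max(state_range) < 2L) stopf("state_range must reach at least 2")
  rows <- list()
  for (n in state_range) for (r in seq_len(replicates)) {
    cfg <- config
    cfg$n_states <- as.integer(n)
    cfg$seed <- derive_seed(seed, n * 1009L + r)
    ens <- engine(restraints, sequence, cfg)
    tf <- target_function(ens, restraints)
    mu <- if (n >= 2L)
      mu_of(ens, n, derive_seed(seed, n * 1009L + r + 499L),
            threshold, restarts) else NA_real_
    rows[[length(rows) + 1L]] <- data.frame(
      n_states = n, replicate = r, target_function = tf$value,
      normalized_target_function = tf$normalized, mu = mu,
      ensemble_rmsd = ensemble_rmsd(ens))
  }
  df <- do.call(rbind, rows)
  smry <- aggregate(df[c("normalized_target_function", "mu",
                         "ensemble_rmsd")],
                    by = list(n_states = df$n_states), FUN = mean)
  sds <- aggregate(df[c("mu")], by = list(n_states = df$n_states),
                   FUN = sd)
  smry$mu_sd <- sds$mu
  with_mu <- smry[!is.na(smry$mu), ]
  optimum <- with_mu$n_states[which.max(with_mu$mu)]
  scan_result(rows, smry, "states", optimum = optimum)
}

# Pick, per conformer and group, the state closest to the group's mean
# coordinates, and assemble the two representatives into a two-state bundle.
group_representatives <- function(ensemble, grouping) {
  M <- ensemble$n_conformers; N <- ensemble$n_states
  L <- nrow(ensemble$atoms)
  arr <- array(NA_real_, dim = c(L, 3L, M * 2L))
  for (m in seq_len(M)) {
    for (gi in 1:2) {
      grp <- if (gi == 1) grouping$A else grouping$B
      idx <- (m - 1L) * N + grp
      gmean <- apply(ensemble$xyz[, , idx, drop = FALSE], c(1, 2), mean)
      dev <- vapply(idx, function(k)
        mean(rowSums((ensemble$xyz[, , k] - gmean)^2)), numeric(1))
      arr[, , (m - 1L) * 2L + gi] <- ensemble$xyz[, , idx[which.min(dev)]]
    }
  }
  ms_ensemble(ensemble$atoms, arr, n_states = 2L)
}

#' Population scan via grouped multi-state calculations
#'
#' Emulates a two-state system with unequal populations by a series of
#' `total_states`-state calculations in which the states are split into two
#' tightly bundled groups A and B; group-A sizes `k = 1..total_states-1`
#' emulate state-A populations `k/total_states`.  From each calculation one
#' representative state per group (the state closest to its group mean) is
#' fed to the correlation engine as a two-state bundle.
#'
#' @inheritParams states_scan
#' @param total_states states per calculation (default 10).
#' @param group_sizes group-A sizes to scan (default `1:9`).
#' @return an `ms_scan` data.frame with columns `group_a_size`,
#'   `population_a`, `replicate`, `target_function`,
#'   `normalized_target_function`, `mu`, `ensemble_rmsd`; attributes
#'   `optimum` (group size maximizing mean mu) and `tf_optimum` (group size
#'   minimizing the mean normalized target function).
#' @export
population_scan <- function(restraints, sequence, config = backend_config(),
                            total_states = 10L, group_sizes = 1:9,
                            replicates = 1L, seed = 0L, threshold = 0.5,
                            restarts = 10L, engine = calculate_ensemble) {
  total_states <- as.integer(total_states)
  if (any(group_sizes < 1L | group_sizes >= total_states))
    stopf("group sizes must lie in 1..%d", total_states - 1L)
  rows <- list()
  for (k in group_sizes) for (r in seq_len(replicates)) {
    cfg <- config
    cfg$n_states <- total_states
    cfg$seed <- derive_seed(seed, k * 2003L + r)
    grouping <- grouping_scheme(seq_len(k), total_states)
    ens <- engine(restraints, sequence, cfg, grouping = grouping)
    tf <- target_function(ens, restraints)
    reps <- group_representatives(ens, grouping)
    mu <- mu_of(reps, 2L, derive_seed(seed, k * 2003L + r + 997L),
                threshold, restarts)
    rows[[length(rows) + 1L]] <- data.frame(
      group_a_size = k, population_a = k / total_states, replicate = r,
      target_function = tf$value,
      normalized_target_function = tf$normalized, mu = mu,
      ensemble_rmsd = ensemble_rmsd(reps))
  }
  df <- do.call(rbind, rows)
  smry <- aggregate(df[c("normalized_target_function", "mu",
                         "ensemble_rmsd")],
                    by = list(group_a_size = df$group_a_size), FUN = mean)
  optimum <- smry$group_a_size[which.max(smry$mu)]
  tf_optimum <- smry$group_a_size[which.min(smry$normalized_target_function)]
  scan_result(rows, smry, "population", optimum = optimum,
              tf_optimum = tf_optimum)
}

#' Restraint titration
#'
#' Recalculates the bundle from random restraint subsets of increasing size
#' (a fresh uniform subsample per replicate) and tracks the ensemble RMSD
#' (which falls as the fold is acquired) and the structural correlation
#' (which rises as the state separation becomes determined).
#'
#' @inheritParams states_scan
#' @param fractions restraint fractions in `(0, 1]`
#'   (default `c(0.03, 0.05, 0.1, 0.2, 0.4, 0.7, 0.9)`).
#' @return an `ms_scan` data.frame with columns `fraction`, `replicate`,
#'   `n_restraints`, `target_function`, `normalized_target_function`, `mu`,
#'   `ensemble_rmsd`, plus a per-fraction `summary` attribute with means
#'   and standard deviations.
#' @export
titration <- function(restraints, sequence, config = backend_config(),
                      fractions = c(0.03, 0.05, 0.1, 0.2, 0.4, 0.7, 0.9),
                      replicates = 10L, seed = 0L, threshold = 0.5,
                      restarts = 10L, engine = calculate_ensemble) {
  if (any(fractions <= 0 | fractions > 1))
    stopf("fractions must lie in (0, 1]")
  if (replicates < 1L) stopf("replicates must be >= 1")
  n_total <- n_restraints(restraints)
  rows <- list()
  for (fi in seq_along(fractions)) {
    f <- fractions[fi]
    n_keep <- round(f * n_total)
    if (n_keep < 1L) {
      warnf("fraction %.3f yields no restraints; condition skipped", f)
      next
    }
    for (r in seq_len(replicates)) {
      sel <- if (n_keep >= n_total) seq_len(n_total) else
        with_seed(derive_seed(seed, fi * 3001L + r),
                  sort(sample.int(n_total, n_keep)))
      sub <- subset_restraints(restraints, sel)
      cfg <- config
      cfg$seed <- derive_seed(seed, fi * 3001L + r + 1499L)
      ens <- engine(sub, sequence, cfg)
      tf <- target_function(ens, sub)
      mu <- if (cfg$n_states >= 2L)
        mu_of(ens, cfg$n_states, derive_seed(seed, fi * 3001L + r + 2953L),
              threshold, restarts) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        fraction = f, replicate = r, n_restraints = n_keep,
        target_function = tf$value,
        normalized_target_function = tf$normalized, mu = mu,
        ensemble_rmsd = ensemble_rmsd(ens))
    }
  }
  if (!length(rows)) stopf("no fraction yielded any restraints")
  df <- do.call(rbind, rows)
  smry <- aggregate(df[c("mu", "ensemble_rmsd")],
                    by = list(fraction = df$fraction), FUN = mean)
  sds <- aggregate(df[c("mu", "ensemble_rmsd")],
                   by = list(fraction = df$fraction), FUN = sd)
  names(sds)[-1] <- c("mu_sd", "ensemble_rmsd_sd")
  smry <- merge(smry, sds, by = "fraction")
  scan_result(rows, smry, "titration")
}

#' Leave-one-out restraint ranking
#'
#' Recalculates the bundle once per in-scope restraint with that restraint
#' removed and records the structural correlation of each depleted
#' calculation.  Removing a restraint removes every limit on the same atom
#' pair (an exact eNOE contributes an upper and a lower limit; omitting the
#' measured distance drops both).  Restraints whose removal depresses mu
#' most are key (state-defining) restraints; restraints whose removal
#' raises mu above the full-set baseline are suspect (possibly inaccurate
#' or misassigned).  The scope is limited to upper limits by default
#' (`scope_types`) so paired lower limits are not ranked twice.
#'
#' @inheritParams states_scan
#' @param long_range_only restrict the scope to restraints with sequence
#'   separation `>= min_separation` (default TRUE).
#' @param min_separation sequence-separation cutoff defining "long-range"
#'   (default 5 residues).
#' @param set_size size of the reported top and bottom sets (default 20;
#'   reduced when the scope is small so the sets stay disjoint).
#' @param common_seed reuse one backend seed for every depleted calculation
#'   (default TRUE) so that ranking differences reflect the removed
#'   restraint, not initialization noise.
#' @param scope_types restraint types eligible for ranking (default
#'   `"upper"`).
#' @return an `ms_ranking` data.frame sorted ascending by `mu_without`
#'   with columns `restraint` (index into the input set), `resid_a`,
#'   `atom_a`, `resid_b`, `atom_b`, `bound`, `mu_without`, `rank`;
#'   attributes `baseline_mu`, `top_set` and `bottom_set` (restraint
#'   indices; top = highest mu_without).
#' @export
loo_ranking <- function(restraints, sequence, config = backend_config(),
                        long_range_only = TRUE, min_separation = 5L,
                        set_size = 20L, seed = 0L, common_seed = TRUE,
                        scope_types = "upper", threshold = 0.5,
                        restarts = 10L, engine = calculate_ensemble) {
  df <- restraints$restraints
  scope <- which(df$type %in% scope_types)
  if (long_range_only)
    scope <- scope[abs(df$resid_a[scope] - df$resid_b[scope]) >=
                     min_separation]
  if (length(scope) < 2L) stopf("fewer than 2 restraints in scope")
  # all limits on the same (unordered) atom pair fall together
  ka <- paste(df$resid_a, df$atom_a); kb <- paste(df$resid_b, df$atom_b)
  pair_key <- ifelse(ka < kb, paste(ka, kb, sep = "|"),
                     paste(kb, ka, sep = "|"))
  cfg <- config
  cfg$seed <- derive_seed(seed, 1L)
  base_ens <- engine(restraints, sequence, cfg)
  baseline_mu <- mu_of(base_ens, cfg$n_states, derive_seed(seed, 2L),
                       threshold, restarts)
  mu_without <- vapply(seq_along(scope), function(si) {
    i <- scope[si]
    drop <- which(pair_key == pair_key[i])
    sub <- subset_restraints(restraints, setdiff(seq_len(nrow(df)), drop))
    cfg$seed <- if (common_seed) derive_seed(seed, 1L)
                else derive_seed(seed, 100L + i)
    ens <- engine(sub, sequence, cfg)
    mu_of(ens, cfg$n_states, derive_seed(seed, 2L), threshold, restarts)
  }, numeric(1))
  ord <- order(mu_without, scope)
  out <- data.frame(restraint = scope, resid_a = df$resid_a[scope],
                    atom_a = df$atom_a[scope], resid_b = df$resid_b[scope],
                    atom_b = df$atom_b[scope], bound = df$bound[scope],
                    mu_without = mu_without)[ord, ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  n <- nrow(out)
  k_bottom <- min(set_size, n)
  k_top <- min(set_size, n - k_bottom)
  structure(out, class = c("ms_ranking", "data.frame"),
            baseline_mu = baseline_mu,
            bottom_set = out$restraint[seq_len(k_bottom)],
            top_set = if (k_top > 0) out$restraint[n - seq_len(k_top) + 1L]
                      else integer(0))
}

#' @export
print.ms_ranking <- function(x, ...) {
  cat(sprintf("Leave-one-out restraint ranking: %d restraints, baseline mu = %.3f\n",
              nrow(x), attr(x, "baseline_mu")))
  cat("lowest mu on removal (key restraints):\n")
  print.data.frame(head(as.data.frame(x), 5), digits = 3)
  cat("highest mu on removal (suspect restraints):\n")
  print.data.frame(tail(as.data.frame(x), 5), digits = 3)
  invisible(x)
}

#' Distance profile of structural correlations
#'
#' Sorts all residue pairs by their ensemble-mean Calpha-Calpha distance,
#' splits them into `n_bins` equal-count groups (remainder pairs go to the
#' last bins) and averages distance and correlation per group, showing over
#' what range correlated motion extends.
#'
#' @param ensemble the [ms_ensemble()] the correlation matrix was computed
#'   from.
#' @param matrix the matching `ms_cormat` (or an `mscor` fit).
#' @param n_bins number of equal-count distance groups (default 10).
#' @return data.frame with columns `bin`, `n_pairs`, `mean_distance`,
#'   `mean_correlation`.
#' @export
distance_profile <- function(ensemble, matrix, n_bins = 10L) {
  if (inherits(matrix, "mscor")) matrix <- matrix$matrix
  stopifnot(inherits(matrix, "ms_cormat"))
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stopf("n_bins must be >= 2")
  D <- distance_array(ensemble, "CA")
  L <- dim(D)[1]
  if (L != nrow(matrix$A))
    stopf("ensemble (%d residues) does not match the matrix (%d)",
          L, nrow(matrix$A))
  Dmean <- apply(D, c(1, 2), mean)
  up <- which(upper.tri(Dmean), arr.ind = TRUE)
  if (nrow(up) < n_bins)
    stopf("fewer residue pairs (%d) than bins (%d)", nrow(up), n_bins)
  dvals <- Dmean[up]
  avals <- matrix$A[up]
  ord <- order(dvals)
  P <- length(ord)
  base <- P %/% n_bins; rem <- P %% n_bins
  sizes <- c(rep(base, n_bins - rem), rep(base + 1L, rem))
  bin <- rep(seq_len(n_bins), times = sizes)
  data.frame(bin = seq_len(n_bins), n_pairs = sizes,
             mean_distance = as.numeric(tapply(dvals[ord], bin, mean)),
             mean_correlation = as.numeric(tapply(avals[ord], bin, mean)))
}

#' Convergence scan over backend effort parameters
#'
#' Computes mu over a grid of optimizer step counts and calculated-conformer
#' counts, flagging the cheapest cell whose mu lies within a tolerance of
#' the maximal-effort cell — the recommended calculation conditions.
#'
#' @inheritParams states_scan
#' @param step_counts optimizer iteration counts to scan.
#' @param conformer_counts calculated-conformer counts to scan (the kept
#'   count is capped at each cell's calculated count).
#' @param tolerance relative mu tolerance for convergence (default 0.05).
#' @return an `ms_scan` data.frame with columns `n_steps`, `n_conformers`,
#'   `mu`, `converged`; attributes `reference_mu` (maximal-effort cell) and
#'   `recommended` (cheapest converged cell, as a named vector).
#' @export
convergence_scan <- function(restraints, sequence, config = backend_config(),
                             step_counts = c(30L, 100L, 300L),
                             conformer_counts = c(100L, 250L, 500L),
                             seed = 0L, tolerance = 0.05, threshold = 0.5,
                             restarts = 10L, engine = calculate_ensemble) {
  if (!length(step_counts) || !length(conformer_counts))
    stopf("step_counts and conformer_counts must be non-empty")
  grid <- expand.grid(n_steps = sort(unique(step_counts)),
                      n_conformers = sort(unique(conformer_counts)))
  mu <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    cfg <- config
    cfg$n_steps <- grid$n_steps[g]
    cfg$n_conformers_calculated <- grid$n_conformers[g]
    cfg$n_conformers_kept <- min(config$n_conformers_kept,
                                 grid$n_conformers[g])
    cfg$seed <- derive_seed(seed, g)
    ens <- engine(restraints, sequence, cfg)
    mu[g] <- if (cfg$n_states >= 2L)
      mu_of(ens, cfg$n_states, derive_seed(seed, g + 5000L),
            threshold, restarts) else NA_real_
  }
  grid$mu <- mu
  ref <- which(grid$n_steps == max(grid$n_steps) &
               grid$n_conformers == max(grid$n_conformers))
  mu_ref <- grid$mu[ref]
  grid$converged <- grid$mu >= mu_ref - tolerance * abs(mu_ref)
  effort <- grid$n_steps * grid$n_conformers
  conv <- which(grid$converged)
  best <- conv[order(effort[conv], grid$n_steps[conv])][1]
  structure(grid, class = c("ms_scan", "data.frame"),
            summary = grid, scan_type = "convergence",
            reference_mu = mu_ref,
            recommended = c(n_steps = grid$n_steps[best],
                            n_conformers = grid$n_conformers[best]))
}

#' Compare a calculation with and without one restraint
#'
#' Runs two otherwise identical backend calculations differing only in the
#' presence of the target restraint and reports the bundle-average target
#' function and structural correlation side by side.  A restraint whose
#' removal barely moves the target function but halves mu is precisely the
#' kind of state-defining restraint the target function alone cannot rank.
#'
#' @inheritParams states_scan
#' @param target index of the restraint to toggle (into the restraint
#'   table).
#' @return data.frame of class `ms_compare` with rows `with` / `without`
#'   and columns `target_function`, `normalized_target_function`, `mu`,
#'   `ensemble_rmsd`.
#' @export
compare_with_without <- function(restraints, target, sequence,
                                 config = backend_config(), seed = 0L,
                                 threshold = 0.5, restarts = 10L,
                                 engine = calculate_ensemble) {
  n <- n_restraints(restraints)
  target <- as.integer(target)
  if (length(target) != 1L || is.na(target) || target < 1L || target > n)
    stopf("target restraint %s not found in the set (1..%d)",
          paste(target, collapse = ","), n)
  run <- function(rs) {
    cfg <- config
    cfg$seed <- derive_seed(seed, 1L)
    ens <- engine(rs, sequence, cfg)
    tf <- target_function(ens, rs)
    data.frame(target_function = tf$value,
               normalized_target_function = tf$normalized,
               mu = if (cfg$n_states >= 2L)
                 mu_of(ens, cfg$n_states, derive_seed(seed, 2L),
                       threshold, restarts) else NA_real_,
               ensemble_rmsd = ensemble_rmsd(ens))
  }
  out <- rbind(run(restraints),
               run(subset_restraints(restraints, setdiff(seq_len(n),
                                                         target))))
  rownames(out) <- c("with", "without")
  structure(out, class = c("ms_compare", "data.frame"),
            target = restraints$restraints[target, ])
}

#' @export
print.ms_compare <- function(x, ...) {
  t <- attr(x, "target")
  cat(sprintf("Restraint %d %s %s - %d %s %s, bound %.2f A:\n",
              t$resid_a, t$resname_a, t$atom_a, t$resid_b, t$resname_b,
              t$atom_b, t$bound))
  print.data.frame(as.data.frame(x), digits = 4)
  invisible(x)
}

#' @export
plot.ms_scan <- function(x, ...) {
  smry <- attr(x, "summary")
  type <- attr(x, "scan_type")
  xvar <- switch(type, states = "n_states", population = "group_a_size",
                 titration = "fraction", convergence = "n_steps")
  op <- par(mar = c(5, 4, 2, 4))
  on.exit(par(op))
  if ("mu" %in% names(smry) && !all(is.na(smry$mu))) {
    plot(smry[[xvar]], smry$mu, type = "b", col = "darkgreen", pch = 16,
         xlab = xvar, ylab = "structural correlation mu", ...)
    if ("normalized_target_function" %in% names(smry)) {
      par(new = TRUE)
      plot(smry[[xvar]], smry$normalized_target_function, type = "b",
           col = "steelblue", pch = 17, axes = FALSE, xlab = "", ylab = "")
      axis(4, col.axis = "steelblue")
      mtext("normalized target function", side = 4, line = 2.5,
            col = "steelblue")
    } else if ("ensemble_rmsd" %in% names(smry)) {
      par(new = TRUE)
      plot(smry[[xvar]], smry$ensemble_rmsd, type = "b", col = "firebrick",
           pch = 17, axes = FALSE, xlab = "", ylab = "")
      axis(4, col.axis = "firebrick")
      mtext("ensemble RMSD [A]", side = 4, line = 2.5, col = "firebrick")
    }
  }
  invisible(x)
}

#' @export
plot.ms_ranking <- function(x, ...) {
  barplot(x$mu_without, names.arg = x$restraint, las = 2,
          col = ifelse(seq_len(nrow(x)) <= length(attr(x, "bottom_set")),
                       "darkgreen",
                       ifelse(seq_len(nrow(x)) > nrow(x) -
                                length(attr(x, "top_set")),
                              "firebrick", "grey70")),
          xlab = "restraint (sorted by mu after removal)",
          ylab = "mu without restraint", ...)
  abline(h = attr(x, "baseline_mu"), lty = 2)
  invisible(x)
}
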