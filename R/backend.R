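# Built-in coarse-grained structure-calculation backend: a Cartesian
# multi-state Calpha-bead minimizer fitting N-state models to r^-6
# ensemble-averaged distance restraints.  It stands in for a full
# torsion-angle-dynamics engine so that the validation assays can run end to
# end; it makes no attempt at all-atom realism.

#' Configuration of the toy structure-calculation backend
#'
#' @param n_states number of states per conformer `N >= 1`.
#' @param n_conformers_calculated conformers minimized (default 500).
#' @param n_conformers_kept best conformers retained by final objective
#'   (default 20).
#' @param n_steps maximum optimizer iterations per conformer (default 300);
#'   the knob scanned by [convergence_scan()].
#' @param bundling_width full width of the flat bottom of the inter-state
#'   bundling potential, Angstrom (default 1.2).
#' @param bundling_weight weight of the (weak) bundling term relative to a
#'   unit restraint weight (default 0.02; weak enough that a handful of
#'   systematically violated restraints can pay for splitting the states).
#' @param chain_bond_length Calpha virtual bond length, Angstrom
#'   (default 3.8).
#' @param steric_min repulsion onset between non-neighbour beads, Angstrom
#'   (default 4.0).
#' @param seed integer seed controlling all random initializations.
#' @param chain_weight weight of the chain-connectivity term (default 10).
#' @param steric_weight weight of the internal steric term (default 1).
#' @param group_bundling_strong,group_bundling_weak bundling weights within /
#'   between the two groups of a grouping scheme (defaults 5 and 0.01).
#' @param sidechain_relaxation bound relaxation, Angstrom, added per non-CA
#'   restraint atom when mapping to beads (default 1.5).
#' @param init_jitter standard deviation, Angstrom, of the random
#'   perturbation applied to the distance-geometry initialization of each
#'   conformer (default 1.0); this is the only source of conformer
#'   diversity.
#' @param optimizer `"lbfgs"` (default, via [stats::optim()]) or `"gd"`
#'   (adaptive backtracking gradient descent with a recorded descent trace).
#' @return list of class `ms_backend_config`.
#' @export
backend_config <- function(n_states = 2L, n_conformers_calculated = 500L,
                           n_conformers_kept = 20L, n_steps = 300L,
                           bundling_width = 1.2, bundling_weight = 0.02,
                           chain_bond_length = 3.8, steric_min = 4.0,
                           seed = 0L, chain_weight = 10, steric_weight = 1,
                           group_bundling_strong = 5,
                           group_bundling_weak = 0.01,
                           sidechain_relaxation = 1.5, init_jitter = 1.0,
                           optimizer = c("lbfgs", "gd")) {
  optimizer <- match.arg(optimizer)
  cfg <- list(n_states = as.integer(n_states),
              n_conformers_calculated = as.integer(n_conformers_calculated),
              n_conformers_kept = as.integer(n_conformers_kept),
              n_steps = as.integer(n_steps),
              bundling_width = bundling_width,
              bundling_weight = bundling_weight,
              chain_bond_length = chain_bond_length,
              steric_min = steric_min, seed = as.integer(seed),
              chain_weight = chain_weight, steric_weight = steric_weight,
              group_bundling_strong = group_bundling_strong,
              group_bundling_weak = group_bundling_weak,
              sidechain_relaxation = sidechain_relaxation,
              init_jitter = init_jitter, optimizer = optimizer)
  with(cfg, {
    if (n_states < 1L || n_conformers_calculated < 1L ||
        n_conformers_kept < 1L || n_steps < 1L)
      stopf("all counts must be >= 1")
    if (n_conformers_kept > n_conformers_calculated)
      stopf("n_conformers_kept (%d) exceeds n_conformers_calculated (%d)",
            n_conformers_kept, n_conformers_calculated)
    if (bundling_width <= 0 || chain_bond_length <= 0 || steric_min <= 0)
      stopf("widths and lengths must be > 0")
  })
  structure(cfg, class = "ms_backend_config")
}

#' Two-group state assignment for population emulation
#'
#' Splits the `1..N` states of a calculation into two controlled groups A
#' and B; states within a group are bundled strongly (they collapse onto a
#' common position), groups are only weakly coupled.  With `N = 10`, group-A
#' sizes 1..9 emulate state-A populations of 10..90%.
#'
#' @param group_a integer state indices forming group A.
#' @param n_states total number of states `N`.
#' @return list of class `ms_grouping` with `A` and `B`.
#' @export
grouping_scheme <- function(group_a, n_states) {
  group_a <- sort(unique(as.integer(group_a)))
  n_states <- as.integer(n_states)
  if (!length(group_a)) stopf("group A must not be empty")
  if (any(group_a < 1L | group_a > n_states))
    stopf("group A states must lie in 1..%d", n_states)
  group_b <- setdiff(seq_len(n_states), group_a)
  if (!length(group_b)) stopf("group B must not be empty")
  structure(list(A = group_a, B = group_b), class = "ms_grouping")
}

# Map restraints onto Calpha beads: non-CA atoms collapse to their residue's
# bead with a bound relaxation per non-CA atom; restraints mapping onto a
# single bead are dropped.
map_restraints_to_beads <- function(restraints, L, relaxation) {
  df <- restraints$restraints
  if (!nrow(df)) {
    return(list(i = integer(), j = integer(), bound = numeric(),
                type = integer(), weight = numeric()))
  }
  bad <- which(df$resid_a < 1L | df$resid_a > L |
               df$resid_b < 1L | df$resid_b > L)
  if (length(bad))
    stopf("restraint %d references residue %d outside the sequence (1..%d)",
          bad[1], max(df$resid_a[bad[1]], df$resid_b[bad[1]]), L)
  relax <- relaxation * ((df$atom_a != "CA") + (df$atom_b != "CA"))
  bound <- df$bound + ifelse(df$type == "upper", relax, -relax)
  keep <- df$resid_a != df$resid_b & bound > 0
  if (any(!keep))
    warnf("%d restraints dropped in bead mapping (same residue or non-positive relaxed bound)",
          sum(!keep))
  type_code <- c(upper = 0L, lower = 1L, steric = 2L)[df$type]
  list(i = df$resid_a[keep] - 1L, j = df$resid_b[keep] - 1L,
       bound = bound[keep], type = unname(type_code[keep]),
       weight = unname(restraints$weights[df$type[keep]]))
}

bundling_matrix <- function(config, grouping) {
  N <- config$n_states
  W <- matrix(config$bundling_weight, N, N)
  if (!is.null(grouping)) {
    # between-group weight is the TOTAL weak coupling between the two
    # groups, spread over the |A| x |B| state pairs, so the effective
    # group-to-group pull does not grow with the group sizes
    W[] <- config$group_bundling_weak /
      (length(grouping$A) * length(grouping$B))
    W[grouping$A, grouping$A] <- config$group_bundling_strong
    W[grouping$B, grouping$B] <- config$group_bundling_strong
  }
  diag(W) <- 0
  W
}

# Distance-geometry initialization: upper bounds and virtual bonds define a
# sparse distance graph; shortest-path smoothing completes it into a full
# metric estimate which classical MDS embeds in 3D.  Random per-conformer
# jitter on this common scaffold provides conformer diversity while keeping
# minimizations inside the fold's basin of attraction.
embed_scaffold <- function(L, beads, bond) {
  D <- matrix(Inf, L, L)
  diag(D) <- 0
  for (i in seq_len(L - 1L)) D[i, i + 1L] <- D[i + 1L, i] <- bond
  up <- which(beads$type == 0L)
  for (r in up) {
    i <- beads$i[r] + 1L; j <- beads$j[r] + 1L
    D[i, j] <- D[j, i] <- min(D[i, j], beads$bound[r])
  }
  for (k in seq_len(L))
    D <- pmin(D, outer(D[, k], D[k, ], `+`))
  if (any(!is.finite(D))) D[!is.finite(D)] <- max(D[is.finite(D)]) * 1.2
  xy <- suppressWarnings(stats::cmdscale(stats::as.dist(D), k = 3L))
  if (ncol(xy) < 3L)
    xy <- cbind(xy, matrix(0, nrow(xy), 3L - ncol(xy)))
  xy
}

eval_objective <- function(coords, L, N, beads, config, W,
                           state_w = rep(1 / N, N)) {
  .ms_objective_cpp(coords, L, N, beads$i, beads$j, beads$bound, beads$type,
                    beads$weight, config$chain_bond_length,
                    config$chain_weight, config$steric_min,
                    config$steric_weight, W, config$bundling_width / 2,
                    state_w)
}

minimize_coords <- function(par, evalfun, config) {
  if (config$optimizer == "gd") {
    res <- gd_minimize(par, evalfun, config$n_steps)
    list(par = res$par, value = res$value)
  } else {
    memo_x <- NULL; memo <- NULL
    cached <- function(x) {
      if (is.null(memo_x) || !identical(x, memo_x)) {
        memo <<- evalfun(x); memo_x <<- x
      }
      memo
    }
    res <- optim(par, fn = function(x) cached(x)$energy,
                 gr = function(x) cached(x)$gradient,
                 method = "L-BFGS-B",
                 control = list(maxit = config$n_steps))
    list(par = res$par, value = res$value)
  }
}

# Adaptive backtracking gradient descent; accepted steps never increase the
# objective.  Returns the final point and the per-step objective trace.
gd_minimize <- function(par, evalfun, n_steps, init_step = 0.02) {
  E <- evalfun(par)$energy
  eta <- init_step
  trace <- numeric(0)
  for (step in seq_len(n_steps)) {
    g <- evalfun(par)$gradient
    gn <- sqrt(sum(g^2))
    if (gn < 1e-10) break
    accepted <- FALSE
    while (eta > 1e-12) {
      trial <- par - eta * g
      Et <- evalfun(trial)$energy
      if (Et <= E) {
        par <- trial; E <- Et; eta <- eta * 1.2; accepted <- TRUE
        break
      }
      eta <- eta / 2
    }
    if (!accepted) break
    trace <- c(trace, E)
  }
  list(par = par, value = E, trace = trace)
}

#' Calculate a multi-state bundle from distance restraints
#'
#' Minimizes, from seeded random compact-chain initializations, the sum of
#' (i) the squared-violation restraint term on r^-6 state-averaged bead
#' distances, (ii) harmonic chain connectivity, (iii) steric repulsion
#' between non-neighbour beads and (iv) flat-bottom bundling between
#' corresponding beads of different states.  The
#' `n_conformers_kept` conformers with the lowest final objective form the
#' returned bundle, mirroring the select-best convention of simulated
#' annealing engines.
#'
#' @param restraints an `ms_restraints` set; non-CA restraint atoms are
#'   mapped to their residue's bead with a relaxed bound.
#' @param sequence residue names (character vector of length `L`) or a
#'   single integer `L` (names default to `"ALA"`).
#' @param config an [backend_config()].
#' @param grouping optional [grouping_scheme()] controlling two-group
#'   bundling for population emulation.
#' @return an [ms_ensemble()] of `n_conformers_kept` conformers with
#'   `n_states` states each, with attributes `objectives` (final objective
#'   of the kept conformers), `all_objectives`, and `config`.
#' @export
calculate_ensemble <- function(restraints, sequence, config = backend_config(),
                               grouping = NULL) {
  stopifnot(inherits(config, "ms_backend_config"))
  if (!is.null(grouping)) {
    stopifnot(inherits(grouping, "ms_grouping"))
    if (max(c(grouping$A, grouping$B)) > config$n_states)
      stopf("grouping references states beyond n_states = %d",
            config$n_states)
  }
  if (is.numeric(sequence) && length(sequence) == 1L)
    sequence <- rep("ALA", as.integer(sequence))
  L <- length(sequence)
  if (L < 2L) stopf("sequence must have at least 2 residues")
  N <- config$n_states
  beads <- map_restraints_to_beads(restraints, L,
                                   config$sidechain_relaxation)
  W <- bundling_matrix(config, grouping)
  n_calc <- config$n_conformers_calculated
  coords_all <- array(NA_real_, dim = c(3L, L, N, n_calc))
  objectives <- numeric(n_calc)
  evalfun <- function(x) eval_objective(x, L, N, beads, config, W)
  scaffold <- embed_scaffold(L, beads, config$chain_bond_length)
  # Grouped calculations are solved in two stages.  Stage 1 minimizes the
  # equivalent weighted two-position problem (the k strongly-bundled states
  # of a group share one position, so the r^-6 average reduces to weights
  # k/N and (N-k)/N on two positions); stage 2 expands each position into
  # its group's states and refines the full N-state system.  Minimizing the
  # N-state system directly from a common start cannot bifurcate the
  # strongly-bundled groups.
  if (!is.null(grouping)) {
    W2 <- matrix(config$group_bundling_weak, 2L, 2L)
    diag(W2) <- 0
    w2 <- c(length(grouping$A), length(grouping$B)) / N
    evalfun2 <- function(x) eval_objective(x, L, 2L, beads, config, W2, w2)
  }
  for (k in seq_len(n_calc)) {
    sk <- derive_seed(config$seed, k)
    par <- with_seed(sk, {
      base <- scaffold + matrix(rnorm(3L * L, sd = config$init_jitter),
                                L, 3L)
      n0 <- if (is.null(grouping)) N else 2L
      as.vector(vapply(seq_len(n0), function(s)
        t(base) + rnorm(3L * L, sd = 0.05), matrix(0, 3L, L)))
    })
    if (is.null(grouping)) {
      res <- minimize_coords(par, evalfun, config)
    } else {
      stage1 <- minimize_coords(par, evalfun2, config)
      pos <- array(stage1$par, dim = c(3L, L, 2L))
      par_full <- with_seed(derive_seed(sk, 2L), {
        full <- array(0, dim = c(3L, L, N))
        for (s in grouping$A)
          full[, , s] <- pos[, , 1L] + rnorm(3L * L, sd = 0.02)
        for (s in grouping$B)
          full[, , s] <- pos[, , 2L] + rnorm(3L * L, sd = 0.02)
        as.vector(full)
      })
      res <- minimize_coords(par_full, evalfun, config)
    }
    coords_all[, , , k] <- array(res$par, dim = c(3L, L, N))
    objectives[k] <- res$value
  }
  full <- beads_to_ensemble(coords_all, sequence)
  out <- rank_and_select(full, objectives, config$n_conformers_kept)
  attr(out, "all_objectives") <- objectives
  attr(out, "config") <- config
  attr(out, "grouping") <- grouping
  out
}

# (3, L, N, M) bead coordinates -> ms_ensemble with conformer-major entities.
beads_to_ensemble <- function(coords, sequence) {
  L <- dim(coords)[2]; N <- dim(coords)[3]; M <- dim(coords)[4]
  arr <- array(NA_real_, dim = c(L, 3L, M * N))
  for (m in seq_len(M)) for (s in seq_len(N))
    arr[, , (m - 1L) * N + s] <- t(coords[, , s, m])
  ca_ensemble(arr, n_states = N, resnames = sequence)
}

#' Select the best conformers of a calculated set
#'
#' Keeps the `keep` conformers with the lowest final objective, in stable
#' order (objective, then calculation index).
#'
#' @param ensemble an [ms_ensemble()] of calculated conformers.
#' @param objectives numeric vector of per-conformer objectives.
#' @param keep number of conformers to retain.
#' @return an [ms_ensemble()] of `keep` conformers with attribute
#'   `objectives` (their objectives, ascending).
#' @export
rank_and_select <- function(ensemble, objectives, keep) {
  M <- ensemble$n_conformers
  if (length(objectives) != M)
    stopf("got %d objectives for %d conformers", length(objectives), M)
  keep <- as.integer(keep)
  if (keep > M) stopf("cannot keep %d of %d conformers", keep, M)
  ord <- order(objectives, seq_len(M))[seq_len(keep)]
  out <- subset_conformers(ensemble, ord)
  attr(out, "objectives") <- objectives[ord]
  out
}
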