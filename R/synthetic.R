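# Synthetic multi-state ground truths: compact self-avoiding Calpha chains
# with a controllable two-state displacement field, thermal noise, state
# populations and eNOE-like restraints -- the test bed for the correlation
# engine and the assays.

# Compact self-avoiding chain: fixed bond length, minimum non-neighbour
# separation enforced by rejection, confined to a sphere so that a
# protein-like contact density arises.
random_chain <- function(L, bond = 3.8, min_sep = 4.0, seed = 0L,
                         radius = NULL, max_restarts = 200L) {
  if (is.null(radius)) radius <- max(2.2 * bond, 2.55 * L^(1 / 3))
  with_seed(seed, {
    for (restart in seq_len(max_restarts)) {
      x <- matrix(NA_real_, L, 3L)
      x[1, ] <- 0
      ok <- TRUE
      for (i in seq_len(L)[-1]) {
        placed <- FALSE
        centroid <- colMeans(x[seq_len(i - 1L), , drop = FALSE])
        for (try in seq_len(200L)) {
          dir <- rnorm(3)
          dir <- dir / sqrt(sum(dir^2))
          cand <- x[i - 1L, ] + bond * dir
          if (sqrt(sum((cand - centroid)^2)) > radius) next
          if (i > 2L) {
            prev <- x[seq_len(i - 2L), , drop = FALSE]
            d2 <- rowSums(sweep(prev, 2, cand)^2)
            if (min(d2) < min_sep^2) next
          }
          x[i, ] <- cand
          placed <- TRUE
          break
        }
        if (!placed) { ok <- FALSE; break }
      }
      if (ok) return(x)
    }
    stopf("failed to generate a self-avoiding chain of length %d", L)
  })
}

# Rodrigues rotation of points about the axis through p0 with unit
# direction u by angle theta.
rotate_about_axis <- function(points, p0, u, theta) {
  v <- sweep(points, 2, p0)
  ct <- cos(theta); st <- sin(theta)
  cross <- cbind(u[2] * v[, 3] - u[3] * v[, 2],
                 u[3] * v[, 1] - u[1] * v[, 3],
                 u[1] * v[, 2] - u[2] * v[, 1])
  dotp <- drop(v %*% u)
  rot <- v * ct + cross * st + outer(dotp * (1 - ct), u)
  sweep(rot, 2, p0, `+`)
}

#' Synthetic two-state ground-truth model
#'
#' Builds a compact self-avoiding Calpha chain (3.8 Angstrom virtual bonds)
#' and a second state in which a contiguous mobile segment swings rigidly
#' about the hinge axis through its two anchor residues.  The hinge rotation
#' preserves every bond length exactly and yields a smooth displacement
#' field that vanishes at the segment ends and peaks (at approximately
#' `displacement`) in the middle.  Candidate segments and rotation angles
#' are screened so the displaced state is clash-free and actually trades
#' short interresidual contacts with the rest of the chain — the structural
#' signature of a genuinely distinct state.  Together with `noise_sigma`,
#' the model controls the signal-to-noise ratio of state separation seen by
#' the correlation engine.
#'
#' @param length number of residues `L >= 8`.
#' @param displacement peak inter-state displacement, Angstrom (`>= 0`; 0
#'   makes the states coincide).  The default of 6 (about 1.6 virtual
#'   bonds) models a large-amplitude hinge motion whose contact trading
#'   clearly exceeds the restraint slack — an unambiguously two-state
#'   system.
#' @param mobile_fraction fraction of residues in the mobile segment,
#'   in `(0, 1]` (default 0.4).
#' @param noise_sigma isotropic thermal noise added per bead when sampling
#'   conformers, Angstrom (default 0.3).
#' @param seed integer seed; the model is deterministic given the seed.
#' @param populations state populations (length 2, summing to 1) used when
#'   deriving ground-truth restraints.
#' @return object of class `ms_model`: list with `base_coords` (`L x 3`),
#'   `state_displacements` (list of `L x 3`, zero outside the mobile
#'   segment), `populations`, `noise_sigma`, `mobile_segment`.
#' @export
make_two_state_model <- function(length = 30L, displacement = 6.0,
                                 mobile_fraction = 0.4, noise_sigma = 0.3,
                                 seed = 0L, populations = c(0.5, 0.5)) {
  L <- as.integer(length)
  if (L < 8L) stopf("length must be >= 8")
  if (displacement < 0) stopf("displacement must be >= 0")
  if (mobile_fraction <= 0 || mobile_fraction > 1)
    stopf("mobile_fraction must lie in (0, 1]")
  if (length(populations) != 2L || any(populations < 0))
    stopf("populations must be two non-negative fractions")
  if (abs(sum(populations) - 1) > 1e-9) stopf("populations must sum to 1")
  bond <- 3.8; min_sep <- 4.0
  n_mob <- max(3L, round(mobile_fraction * L))
  n_mob <- min(n_mob, L - 2L)  # hinge anchors must exist on both sides
  # A frustrated (state-encoding) motion needs close contacts lost AND
  # gained: pairs tight in A that open in B, and vice versa, pull any
  # single-state compromise in opposite directions.  Base chains and hinges
  # are screened until such a motion is found.
  two_sided_contrast <- function(dA, dB, ut) {
    c(nA = sum(ut & dA <= 5.5 & dB - dA >= 1),
      nB = sum(ut & dB <= 5.5 & dA - dB >= 1))
  }
  best <- NULL
  n_chain_tries <- if (displacement > 0) 30L else 1L
  for (chain_try in seq_len(n_chain_tries)) {
    base <- random_chain(L, bond = bond, min_sep = min_sep,
                         seed = derive_seed(seed, 11L + chain_try))
    if (displacement == 0) {
      best <- list(base = base, cand = NULL,
                   seg = (2L + (L - n_mob - 2L) %/% 2L) + seq_len(n_mob) - 1L)
      break
    }
    dA <- as.matrix(dist(base))
    ut <- upper.tri(dA)
    cand_best <- with_seed(derive_seed(seed, 31L + chain_try), {
      starts <- sample(2L:(L - n_mob))  # all feasible hinge positions
      found <- NULL
      for (start in starts) {
        seg <- start:(start + n_mob - 1L)
        p0 <- base[start - 1L, ]
        axis <- base[max(seg) + 1L, ] - p0
        axis <- axis / sqrt(sum(axis^2))
        # angle giving the requested peak displacement for this hinge
        v <- sweep(base[seg, , drop = FALSE], 2, p0)
        r <- sqrt(rowSums((v - outer(drop(v %*% axis), axis))^2))
        r_max <- max(r)
        if (r_max < 1e-6) next
        th0 <- 2 * asin(min(1, displacement / (2 * r_max)))
        for (theta in c(th0, -th0, 0.75 * th0, -0.75 * th0,
                        0.5 * th0, -0.5 * th0)) {
          cand <- base
          cand[seg, ] <- rotate_about_axis(base[seg, , drop = FALSE],
                                           p0, axis, theta)
          dmat <- as.matrix(dist(cand))
          dmat[abs(row(dmat) - col(dmat)) <= 1L] <- Inf
          if (min(dmat) < 0.95 * min_sep) next
          realized <- max(sqrt(rowSums((cand - base)^2)))
          ts <- two_sided_contrast(dA, as.matrix(dist(cand)), ut)
          score <- 2 * min(ts) + 0.1 * sum(ts) +
            2 * (realized >= 0.7 * displacement)
          if (is.null(found) || score > found$score)
            found <- list(base = base, cand = cand, seg = seg,
                          score = score, two_sided = min(ts))
        }
      }
      found
    })
    if (!is.null(cand_best) &&
        (is.null(best) || cand_best$score > best$score)) best <- cand_best
    if (!is.null(best) && (best$two_sided %||% 0) >= 8L) break
  }
  if (is.null(best))
    stopf("could not place a clash-free displaced state; try another seed")
  base <- best$base
  seg <- best$seg
  disp2 <- matrix(0, L, 3L)
  if (!is.null(best$cand)) {
    disp2 <- best$cand - base
    disp2[-seg, ] <- 0
  }
  structure(list(base_coords = base,
                 state_displacements = list(matrix(0, L, 3L), disp2),
                 populations = populations / sum(populations),
                 noise_sigma = noise_sigma,
                 mobile_segment = seg, seed = as.integer(seed)),
            class = "ms_model")
}

#' @export
print.ms_model <- function(x, ...) {
  peak <- max(sqrt(rowSums(x$state_displacements[[2]]^2)))
  cat(sprintf("Synthetic %d-state model: %d residues, mobile segment %d-%d, peak displacement %.2f A, noise %.2f A, populations %s\n",
              length(x$state_displacements), nrow(x$base_coords),
              min(x$mobile_segment), max(x$mobile_segment), peak,
              x$noise_sigma,
              paste(sprintf("%.0f%%", 100 * x$populations), collapse = "/")))
  invisible(x)
}

#' Ground-truth state coordinates of a synthetic model
#' @param model an `ms_model`.
#' @return list of `L x 3` coordinate matrices, one per state.
#' @export
model_states <- function(model) {
  lapply(model$state_displacements, function(d) model$base_coords + d)
}

#' Sample a noisy multi-state ensemble from a synthetic model
#'
#' Every conformer holds one copy of each ground-truth state with i.i.d.
#' isotropic Gaussian noise of `model$noise_sigma` on every bead, laid out
#' in the package's conformer-major entity convention.
#'
#' @param model an `ms_model` from [make_two_state_model()].
#' @param n_conformers number of conformers `M`.
#' @param seed integer seed.
#' @return an [ms_ensemble()] with `M x N` entities.
#' @export
sample_ensemble <- function(model, n_conformers, seed = 0L) {
  states <- model_states(model)
  N <- length(states); L <- nrow(model$base_coords)
  M <- as.integer(n_conformers)
  arr <- array(NA_real_, dim = c(L, 3L, M * N))
  with_seed(derive_seed(seed, 41L), {
    for (m in seq_len(M)) for (s in seq_len(N))
      arr[, , (m - 1L) * N + s] <- states[[s]] +
        matrix(rnorm(3L * L, sd = model$noise_sigma), L, 3L)
  })
  ca_ensemble(arr, n_states = N)
}

#' Derive eNOE-like distance restraints from a synthetic ground truth
#'
#' For every residue pair whose population-weighted r^-6 average Calpha
#' distance over the ground-truth states lies within the contact cutoff, an
#' upper limit is placed at that averaged distance plus a small slack.  At
#' equal populations the weighted average is exactly the equal-weight r^-6
#' state average.  A random subset can be retained and selected bounds can
#' be corrupted (rescaled) to emulate misassigned restraints.
#'
#' @param model an `ms_model`.
#' @param contact_cutoff proton-level contact cutoff in Angstrom (default
#'   5, the range of a single NOE).
#' @param bead_correction Angstrom added to the cutoff at the Calpha-bead
#'   level (default 3 = 1.5 per atom, mirroring the backend's bead-mapping
#'   relaxation): protons up to 5 Angstrom apart sit on residues whose
#'   Calpha atoms can be several Angstrom further apart, so restraints at
#'   bead resolution capture a correspondingly wider distance shell.
#' @param fraction fraction of eligible restraints kept, in `(0, 1]`.
#' @param corrupt optional corruption spec: data.frame with columns `index`
#'   (into the returned restraint set) and `scale` (bound multiplier).
#' @param slack additive slack on the bound, Angstrom (default 0.1).
#' @param lower_limits if TRUE (default), each contact also yields the
#'   matching lower limit at the averaged distance minus the slack, making
#'   the restraint an eNOE-like exact distance; FALSE gives upper limits
#'   only.  Corruption indices refer to upper limits; both limits of a
#'   corrupted contact are rescaled together, emulating a misassigned
#'   exact distance (the measured value is wrong, so the whole window
#'   moves).
#' @param seed integer seed for the random subsample.
#' @return an `ms_restraints` set of CA-CA limits; upper limits first, then
#'   any paired lower limits.
#' @export
restraints_from_model <- function(model, contact_cutoff = 5.0,
                                  bead_correction = 3.0, fraction = 1.0,
                                  corrupt = NULL, slack = 0.1,
                                  lower_limits = TRUE, seed = 0L) {
  if (fraction <= 0 || fraction > 1) stopf("fraction must lie in (0, 1]")
  contact_cutoff <- contact_cutoff + bead_correction
  states <- model_states(model)
  L <- nrow(model$base_coords)
  pairs <- which(upper.tri(matrix(0, L, L)), arr.ind = TRUE)
  dmats <- lapply(states, function(s) as.matrix(dist(s)))
  dstar <- vapply(seq_len(nrow(pairs)), function(p) {
    ds <- vapply(dmats, function(D) D[pairs[p, 1], pairs[p, 2]], numeric(1))
    r6_average(ds, weights = model$populations)
  }, numeric(1))
  keep <- which(dstar <= contact_cutoff)
  if (!length(keep)) stopf("no residue pair within the contact cutoff")
  df <- data.frame(resid_a = pairs[keep, 1], resname_a = "ALA",
                   atom_a = "CA", resid_b = pairs[keep, 2],
                   resname_b = "ALA", atom_b = "CA",
                   bound = dstar[keep] + slack, type = "upper",
                   stringsAsFactors = FALSE)
  if (fraction < 1) {
    n_keep <- max(1L, round(fraction * nrow(df)))
    sel <- with_seed(derive_seed(seed, 53L),
                     sort(sample.int(nrow(df), n_keep)))
    df <- df[sel, , drop = FALSE]
  }
  rownames(df) <- NULL
  corrupted <- integer(0)
  if (!is.null(corrupt)) {
    corrupt <- as.data.frame(corrupt)
    if (!all(c("index", "scale") %in% names(corrupt)))
      stopf("corrupt must have columns index and scale")
    if (any(corrupt$index < 1L | corrupt$index > nrow(df)))
      stopf("corruption index out of range 1..%d", nrow(df))
    df$bound[corrupt$index] <- df$bound[corrupt$index] * corrupt$scale
    corrupted <- corrupt$index
  }
  if (lower_limits) {
    lo <- df
    lo$type <- "lower"
    lo$bound <- pmax(lo$bound - 2 * slack, 1.0)
    if (length(corrupted))  # lower = scale * (d - slack) for corrupted pairs
      lo$bound[corrupted] <- pmax(df$bound[corrupted] -
                                    2 * slack * corrupt$scale, 1.0)
    df <- rbind(df, lo)
    rownames(df) <- NULL
  }
  restraint_set(df)
}
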