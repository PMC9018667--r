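# Fixture builders shared across the test files.  Everything is generated in
# code; no binary fixtures.

# Bead (CA-only) ensemble from a list of L x 3 coordinate matrices given in
# conformer-major entity order.
bead_ensemble <- function(coord_list, n_states = 1L) {
  L <- nrow(coord_list[[1]])
  atoms <- data.frame(chain = "A", resid = seq_len(L), resname = "ALA",
                      name = "CA", stringsAsFactors = FALSE)
  arr <- array(NA_real_, dim = c(L, 3L, length(coord_list)))
  for (k in seq_along(coord_list)) arr[, , k] <- coord_list[[k]]
  ms_ensemble(atoms, arr, n_states = n_states)
}

# Compact random bead cloud used as a generic fold.
random_fold <- function(L, seed, scale = 6) {
  set.seed(seed)
  matrix(rnorm(3 * L, sd = scale), L, 3L)
}

# Two-state ensemble in which EVERY residue separates: states are two
# unrelated folds, so all interresidual distances differ by much more than
# the thermal noise.  M conformers x 2 states, conformer-major.
rigid_two_state_ensemble <- function(M = 20, L = 20, noise = 0.3,
                                     seed = 1) {
  sA <- random_fold(L, seed)
  sB <- random_fold(L, seed + 1000)
  set.seed(seed + 2000)
  coords <- vector("list", 2 * M)
  for (m in seq_len(M)) {
    coords[[2 * m - 1]] <- sA + matrix(rnorm(3 * L, sd = noise), L, 3)
    coords[[2 * m]] <- sB + matrix(rnorm(3 * L, sd = noise), L, 3)
  }
  bead_ensemble(coords, n_states = 2L)
}

# Stateless control: one fold plus i.i.d. Gaussian noise on every entity.
noise_ensemble <- function(M = 20, L = 20, noise = 1.0, seed = 1) {
  s <- random_fold(L, seed)
  set.seed(seed + 3000)
  coords <- lapply(seq_len(2 * M), function(k)
    s + matrix(rnorm(3 * L, sd = noise), L, 3))
  bead_ensemble(coords, n_states = 2L)
}

# Independent brute-force mutual information (bits), written as explicit
# loops over label values -- the oracle for the table-based implementation.
brute_force_mi <- function(x, y) {
  n <- length(x)
  total <- 0
  for (a in unique(x)) for (b in unique(y)) {
    pxy <- sum(x == a & y == b) / n
    if (pxy == 0) next
    px <- sum(x == a) / n
    py <- sum(y == b) / n
    total <- total + pxy * log2(pxy / (px * py))
  }
  total
}

# Small restraint table helper.
upl <- function(ra, rb, bound, type = "upper", atom = "CA") {
  if (!length(ra)) {
    return(data.frame(resid_a = integer(), resname_a = character(),
                      atom_a = character(), resid_b = integer(),
                      resname_b = character(), atom_b = character(),
                      bound = numeric(), type = character(),
                      stringsAsFactors = FALSE))
  }
  data.frame(resid_a = ra, resname_a = "ALA", atom_a = atom,
             resid_b = rb, resname_b = "ALA", atom_b = atom,
             bound = bound, type = type, stringsAsFactors = FALSE)
}
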