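#' Multi-state ensemble container
#'
#' An `ms_ensemble` holds a bundle of `M` conformers, each consisting of `N`
#' conformational states of the same protein.  Every state of every conformer
#' is one *entity*; entities are stored conformer-major (conformer 1 state 1,
#' conformer 1 state 2, ..., conformer 2 state 1, ...), the order in which a
#' multi-state calculation deposits them and the order in which the
#' correlation engine consumes them.
#'
#' @param atoms data.frame with columns `chain`, `resid` (integer residue
#'   number), `resname` (3-letter code) and `name` (PDB atom name), one row
#'   per atom; the atom template shared by all entities.
#' @param xyz numeric array `n_atoms x 3 x n_entities` of coordinates in
#'   Angstrom.
#' @param n_states integer, number of states per conformer (`N >= 1`).
#'
#' @return An object of class `ms_ensemble` with elements `atoms`, `xyz`,
#'   `n_states`, `n_conformers`.
#' @seealso [read_ensemble()], [entities()], [mscor()]
#' @export
ms_ensemble <- function(atoms, xyz, n_states = 1L) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  req <- c("chain", "resid", "resname", "name")
  if (!all(req %in% names(atoms)))
    stopf("atoms must have columns %s", paste(req, collapse = ", "))
  if (length(dim(xyz)) != 3L || dim(xyz)[2] != 3L)
    stopf("xyz must be an n_atoms x 3 x n_entities array")
  if (dim(xyz)[1] != nrow(atoms))
    stopf("xyz has %d atoms but the atom template has %d rows",
          dim(xyz)[1], nrow(atoms))
  n_entities <- dim(xyz)[3]
  if (n_entities < 1L) stopf("ensemble must contain at least one entity")
  if (!all(is.finite(xyz))) stopf("all coordinates must be finite")
  if (any(atoms$resid < 1L)) stopf("residue indices must be >= 1")
  if (is.unsorted(atoms$resid)) stopf("residue indices must be non-decreasing")
  n_states <- as.integer(n_states)
  if (n_states < 1L) stopf("n_states must be >= 1")
  if (n_entities %% n_states != 0L)
    stopf("entity count %d is not divisible by n_states = %d",
          n_entities, n_states)
  structure(
    list(atoms = atoms, xyz = xyz, n_states = n_states,
         n_conformers = n_entities %/% n_states),
    class = "ms_ensemble")
}

#' @export
print.ms_ensemble <- function(x, ...) {
  cat(sprintf(
    "Multi-state ensemble: %d conformers x %d states (%d entities)\n",
    x$n_conformers, x$n_states, x$n_conformers * x$n_states))
  rt <- residue_table(x$atoms)
  cat(sprintf("  %d residues (%d-%d), %d atoms per entity\n",
              nrow(rt), min(rt$resid), max(rt$resid), nrow(x$atoms)))
  invisible(x)
}

# One residue per row, in chain order.
residue_table <- function(atoms) {
  keep <- !duplicated(atoms$resid)
  data.frame(resid = atoms$resid[keep], resname = atoms$resname[keep],
             stringsAsFactors = FALSE)
}

#' Number of residues in an ensemble
#' @param ensemble an [ms_ensemble()].
#' @return integer sequence length `L`.
#' @export
sequence_length <- function(ensemble) {
  nrow(residue_table(ensemble$atoms))
}

#' Extract a single entity as a state model
#'
#' @param ensemble an [ms_ensemble()].
#' @param conformer conformer index in `1..M`.
#' @param state state index in `1..N`.
#' @return An object of class `ms_state`: list with `atoms` (template
#'   data.frame), `xyz` (`n_atoms x 3` matrix), `conformer`, `state_index`.
#' @export
get_entity <- function(ensemble, conformer, state = 1L) {
  M <- ensemble$n_conformers; N <- ensemble$n_states
  if (conformer < 1L || conformer > M) stopf("conformer index out of range")
  if (state < 1L || state > N) stopf("state index out of range")
  k <- (conformer - 1L) * N + state
  structure(list(atoms = ensemble$atoms,
                 xyz = matrix(ensemble$xyz[, , k], ncol = 3L),
                 conformer = as.integer(conformer),
                 state_index = as.integer(state)),
            class = "ms_state")
}

#' List all entities of an ensemble
#'
#' Returns the `M x N` entities in the canonical conformer-major, state-minor
#' order (c1s1, c1s2, ..., c2s1, ...), the unit on which residue-wise
#' clustering and correlations operate.
#'
#' @param ensemble an [ms_ensemble()].
#' @return list of `ms_state` objects of length `M * N`.
#' @export
entities <- function(ensemble) {
  M <- ensemble$n_conformers; N <- ensemble$n_states
  out <- vector("list", M * N)
  for (m in seq_len(M)) for (s in seq_len(N))
    out[[(m - 1L) * N + s]] <- get_entity(ensemble, m, s)
  out
}

#' Keep a subset of conformers
#' @param ensemble an [ms_ensemble()].
#' @param which integer conformer indices to keep (order respected).
#' @return An [ms_ensemble()] with `length(which)` conformers.
#' @export
subset_conformers <- function(ensemble, which) {
  N <- ensemble$n_states
  if (any(which < 1L | which > ensemble$n_conformers))
    stopf("conformer index out of range")
  cols <- as.vector(vapply(which, function(m) (m - 1L) * N + seq_len(N),
                           integer(N)))
  ms_ensemble(ensemble$atoms, ensemble$xyz[, , cols, drop = FALSE], N)
}

#' Read a multi-state ensemble from a multi-model PDB file
#'
#' Two dialects are supported for encoding `N` states per conformer:
#' `"models"` (default) groups consecutive `MODEL` blocks `N` at a time, so a
#' file with `M * N` models yields `M` conformers; `"chains"` expects one
#' `MODEL` per conformer containing `N` chains of identical composition, one
#' chain per state.
#'
#' @param path path to a PDB file with `MODEL`/`ENDMDL` records.
#' @param states_per_conformer integer `N >= 1`.
#' @param dialect `"models"` or `"chains"` (see Details).
#' @return An [ms_ensemble()].
#' @examples
#' mdl <- make_two_state_model(length = 10, seed = 1)
#' ens <- sample_ensemble(mdl, n_conformers = 3, seed = 1)
#' f <- tempfile(fileext = ".pdb")
#' write_ensemble(ens, f)
#' read_ensemble(f, states_per_conformer = 2)
#' @export
read_ensemble <- function(path, states_per_conformer = 1L,
                          dialect = c("models", "chains")) {
  dialect <- match.arg(dialect)
  N <- as.integer(states_per_conformer)
  if (N < 1L) stopf("states_per_conformer must be >= 1")
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE))
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  n_models <- nrow(xyz)
  at <- pdb$atom
  atoms <- data.frame(chain = ifelse(is.na(at$chain), "A", at$chain),
                      resid = at$resno, resname = at$resid, name = at$elety,
                      stringsAsFactors = FALSE)
  if (dialect == "models") {
    if (n_models %% N != 0L)
      stopf("model count %d is not divisible by states_per_conformer = %d",
            n_models, N)
    arr <- array(NA_real_, dim = c(nrow(atoms), 3L, n_models))
    for (k in seq_len(n_models))
      arr[, , k] <- matrix(xyz[k, ], ncol = 3L, byrow = TRUE)
    ms_ensemble(atoms, arr, n_states = N)
  } else {
    chains <- unique(atoms$chain)
    if (length(chains) != N)
      stopf("file has %d chains per model but states_per_conformer = %d",
            length(chains), N)
    idx <- lapply(chains, function(ch) which(atoms$chain == ch))
    n0 <- length(idx[[1]])
    tmpl <- atoms[idx[[1]], , drop = FALSE]
    for (s in seq_along(idx)[-1]) {
      a <- atoms[idx[[s]], , drop = FALSE]
      if (nrow(a) != n0)
        stopf("chain %s has %d atoms but chain %s has %d",
              chains[s], nrow(a), chains[1], n0)
      bad <- which(a$resname != tmpl$resname | a$name != tmpl$name)
      if (length(bad))
        stopf("heterogeneous atom composition: chain %s differs from chain %s first at residue %d (%s %s vs %s %s)",
              chains[s], chains[1], tmpl$resid[bad[1]],
              a$resname[bad[1]], a$name[bad[1]],
              tmpl$resname[bad[1]], tmpl$name[bad[1]])
    }
    tmpl$chain <- chains[1]
    arr <- array(NA_real_, dim = c(n0, 3L, n_models * N))
    for (m in seq_len(n_models)) {
      coords <- matrix(xyz[m, ], ncol = 3L, byrow = TRUE)
      for (s in seq_len(N))
        arr[, , (m - 1L) * N + s] <- coords[idx[[s]], , drop = FALSE]
    }
    ms_ensemble(tmpl, arr, n_states = N)
  }
}

#' Write an ensemble to a multi-model PDB file
#'
#' Entities are written conformer-major, one `MODEL` per entity (the
#' `"models"` dialect of [read_ensemble()]); coordinates are stored at the
#' PDB format's 3-decimal precision.
#'
#' @param ensemble an [ms_ensemble()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(ensemble, path) {
  n_ent <- dim(ensemble$xyz)[3]
  flat <- t(apply(ensemble$xyz, 3, function(m) as.vector(t(m))))
  if (n_ent == 1L) flat <- matrix(flat, nrow = 1L)
  at <- ensemble$atoms
  bio3d::write.pdb(file = path, xyz = flat, resno = at$resid,
                   resid = at$resname, elety = at$name, chain = at$chain)
  invisible(path)
}

# Build a CA-bead ensemble from an array of per-entity bead coordinates
# (dim L x 3 x n_entities).
ca_ensemble <- function(coords, n_states, resnames = NULL) {
  L <- dim(coords)[1]
  if (is.null(resnames)) resnames <- rep("ALA", L)
  atoms <- data.frame(chain = "A", resid = seq_len(L), resname = resnames,
                      name = "CA", stringsAsFactors = FALSE)
  ms_ensemble(atoms, coords, n_states = n_states)
}
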