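#' Reference coordinates of every residue in one entity
#'
#' @param state an `ms_state` (see [get_entity()]).
#' @param atom_mode `"CA"` (default), `"CB"` (Cbeta, falling back to Calpha
#'   for glycine) or `"centroid"` (mean of heavy atoms).
#' @return `L x 3` matrix of reference-atom coordinates, one row per residue.
#' @keywords internal
residue_coords <- function(state, atom_mode = c("CA", "CB", "centroid")) {
  atom_mode <- match.arg(atom_mode)
  at <- state$atoms
  xyz <- state$xyz
  resids <- unique(at$resid)
  out <- matrix(NA_real_, length(resids), 3L)
  for (i in seq_along(resids)) {
    rows <- which(at$resid == resids[i])
    sel <- switch(atom_mode,
      CA = rows[at$name[rows] == "CA"],
      CB = {
        r <- rows[at$name[rows] == "CB"]
        if (!length(r)) rows[at$name[rows] == "CA"] else r
      },
      centroid = rows[!grepl("^[0-9]*H", at$name[rows])])
    if (!length(sel))
      stopf("residue %d (%s) has no %s reference atom",
            resids[i], at$resname[rows[1]], atom_mode)
    out[i, ] <- colMeans(xyz[sel, , drop = FALSE])
  }
  rownames(out) <- resids
  out
}

#' Interresidual distance matrix of one entity
#'
#' Euclidean distances between the reference atoms of all residue pairs, the
#' raw feature from which state clusterings are built.
#'
#' @inheritParams residue_coords
#' @return symmetric `L x L` matrix of distances in Angstrom with zero
#'   diagonal.
#' @export
residue_distance_matrix <- function(state, atom_mode = c("CA", "CB", "centroid")) {
  rc <- residue_coords(state, atom_mode)
  as.matrix(dist(rc))
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares superposition of `mobile` onto `reference`, constrained to a
#' proper rotation (determinant +1).
#'
#' @param mobile,reference `n x 3` coordinate matrices, `n >= 3`.
#' @return list with `rotation` (3x3, det +1), `translation` (length-3), and
#'   `rmsd` after fitting; the fitted coordinates are
#'   `mobile %*% rotation + translation` (row-wise).
#' @export
superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference))
    stopf("point counts differ (%d vs %d)", nrow(mobile), nrow(reference))
  if (nrow(mobile) < 3L) stopf("at least 3 points are required")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  A <- sweep(mobile, 2, cm); B <- sweep(reference, 2, cr)
  H <- crossprod(A, B)
  sv <- svd(H)
  if (sv$d[2] < 1e-12) stopf("degenerate (rank-deficient) point set")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  fitted <- A %*% R
  rmsd <- sqrt(mean(rowSums((fitted - B)^2)))
  list(rotation = R, translation = as.numeric(cr - cm %*% R), rmsd = rmsd)
}

# Apply a superposition of `coords` onto `reference` and return the fitted
# coordinates.
superpose_coords <- function(coords, reference) {
  fit <- superpose(coords, reference)
  sweep(coords %*% fit$rotation, 2, fit$translation, `+`)
}

#' Ensemble RMSD of a bundle
#'
#' Spread of the bundle, defined as the mean over all entities of the RMSD to
#' the mean structure; every entity is superposed onto the running mean,
#' which is re-estimated for `iterations` passes.  A pairwise definition
#' (mean RMSD over all entity pairs after pairwise superposition) is
#' available via `method = "pairwise"`.
#'
#' @param ensemble an [ms_ensemble()] with at least 2 entities.
#' @param atom_selection `"CA"` (default) or `"backbone"` (N, CA, C, O).
#' @param method `"mean"` (default) or `"pairwise"`.
#' @param iterations mean-structure refinement passes (default 3).
#' @return RMSD in Angstrom.
#' @export
ensemble_rmsd <- function(ensemble, atom_selection = c("CA", "backbone"),
                          method = c("mean", "pairwise"), iterations = 3L) {
  atom_selection <- match.arg(atom_selection)
  method <- match.arg(method)
  n_ent <- dim(ensemble$xyz)[3]
  if (n_ent < 2L) stopf("ensemble RMSD requires at least 2 entities")
  sel <- if (atom_selection == "CA") which(ensemble$atoms$name == "CA")
         else which(ensemble$atoms$name %in% c("N", "CA", "C", "O"))
  if (length(sel) < 3L) stopf("fewer than 3 atoms in selection")
  sets <- lapply(seq_len(n_ent), function(k) ensemble$xyz[sel, , k])
  if (method == "pairwise") {
    tot <- 0; np <- 0L
    for (i in seq_len(n_ent - 1L)) for (j in (i + 1L):n_ent) {
      tot <- tot + superpose(sets[[i]], sets[[j]])$rmsd
      np <- np + 1L
    }
    return(tot / np)
  }
  ref <- sets[[1]]
  fitted <- sets
  for (it in seq_len(iterations)) {
    fitted <- lapply(sets, superpose_coords, reference = ref)
    ref <- Reduce(`+`, fitted) / n_ent
  }
  mean(vapply(fitted, function(m) sqrt(mean(rowSums((m - ref)^2))),
              numeric(1)))
}
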