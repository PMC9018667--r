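# The correlation engine: residue-wise clustering of entities on
# interresidual distances, adjusted-mutual-information matrix A, and the
# scalar structural correlation parameter mu.

# L x L x n_entities array of interresidual distances, one slice per entity.
distance_array <- function(ensemble, atom_mode = "CA") {
  at <- ensemble$atoms
  n_ent <- dim(ensemble$xyz)[3]
  # fast path: pure reference-atom (bead) ensembles
  if (atom_mode == "CA" && all(at$name == "CA")) {
    L <- nrow(at)
    D <- array(0, dim = c(L, L, n_ent))
    for (k in seq_len(n_ent))
      D[, , k] <- as.matrix(dist(ensemble$xyz[, , k]))
    return(D)
  }
  ent <- entities(ensemble)
  rc1 <- residue_coords(ent[[1]], atom_mode)
  L <- nrow(rc1)
  D <- array(0, dim = c(L, L, n_ent))
  D[, , 1] <- as.matrix(dist(rc1))
  for (k in seq_len(n_ent)[-1])
    D[, , k] <- as.matrix(dist(residue_coords(ent[[k]], atom_mode)))
  D
}

feature_matrix <- function(D, residue, threshold) {
  Fm <- t(D[residue, -residue, , drop = TRUE])
  if (is.null(dim(Fm))) Fm <- matrix(Fm, ncol = 1L)
  sds <- apply(Fm, 2, sd)
  Fm[, sds >= threshold, drop = FALSE]
}

#' Distance features of one residue across all entities
#'
#' One row per entity holding the distances from the selected residue to
#' every other residue; features whose standard deviation across entities
#' falls below the significance threshold (default 0.5 Angstrom, screening
#' out random thermal motion) are removed.
#'
#' @param ensemble an [ms_ensemble()].
#' @param residue residue position (1-based index into the residue list).
#' @param threshold significance threshold in Angstrom (default 0.5); a
#'   threshold of 0 retains all features.
#' @param atom_mode reference atom for interresidual distances, see
#'   [residue_distance_matrix()].
#' @return numeric matrix `n_entities x n_retained`; may have zero columns
#'   when the ensemble shows no significant motion around the residue.
#' @export
residue_features <- function(ensemble, residue, threshold = 0.5,
                             atom_mode = "CA") {
  L <- sequence_length(ensemble)
  if (residue < 1L || residue > L)
    stopf("residue index %d out of range 1..%d", residue, L)
  if (threshold < 0) stopf("threshold must be >= 0")
  D <- distance_array(ensemble, atom_mode)
  feature_matrix(D, residue, threshold)
}

#' Adjusted-mutual-information correlation matrix
#'
#' For each of the `L` residues the `M x N` entities are clustered into
#' `n_states` groups on that residue's distance features
#' ([residue_features()], [cluster_entities()]); entry `A[i, j]` is the
#' adjusted mutual information between the clusterings of residues `i` and
#' `j`.  Residues whose features are entirely filtered out (no motion above
#' the significance threshold) yield degenerate clusterings and zero rows.
#'
#' @param ensemble an [ms_ensemble()] with at least `n_states` entities.
#' @param n_states number of clusters `K >= 2` (the assumed state count).
#' @param threshold significance threshold in Angstrom (default 0.5).
#' @param seed integer seed for the clustering restarts.
#' @param atom_mode reference atom, default `"CA"`.
#' @param restarts GMM restarts per residue (default 10).
#' @return object of class `ms_cormat`: list with `A` (symmetric `L x L`
#'   matrix, unit diagonal on non-degenerate rows), `clusterings` (list of
#'   per-residue label vectors), `degenerate` (logical per residue),
#'   `residues`, `n_states`, `threshold`.
#' @export
correlation_matrix <- function(ensemble, n_states = 2L, threshold = 0.5,
                               seed = 0L, atom_mode = "CA", restarts = 10L) {
  K <- as.integer(n_states)
  if (K < 2L)
    stopf("at least two states are required for the meaningful extraction of structural correlations (got n_states = %d)", K)
  n_ent <- dim(ensemble$xyz)[3]
  if (n_ent < K)
    stopf("ensemble has %d entities, fewer than n_states = %d", n_ent, K)
  D <- distance_array(ensemble, atom_mode)
  L <- dim(D)[1]
  clusterings <- vector("list", L)
  degenerate <- logical(L)
  for (r in seq_len(L)) {
    Fm <- feature_matrix(D, r, threshold)
    lab <- cluster_entities(Fm, K, seed = derive_seed(seed, r),
                            restarts = restarts)
    clusterings[[r]] <- lab
    degenerate[r] <- isTRUE(attr(lab, "uninformative"))
  }
  A <- matrix(0, L, L)
  for (i in seq_len(L)) {
    if (!degenerate[i]) A[i, i] <- 1
    if (i < L) for (j in (i + 1L):L) {
      if (degenerate[i] || degenerate[j]) next
      A[i, j] <- A[j, i] <-
        adjusted_mutual_information(clusterings[[i]], clusterings[[j]])
    }
  }
  rt <- residue_table(ensemble$atoms)
  structure(list(A = A, clusterings = clusterings, degenerate = degenerate,
                 residues = rt$resid, n_states = K, threshold = threshold),
            class = "ms_cormat")
}

#' @export
print.ms_cormat <- function(x, ...) {
  cat(sprintf("Structural correlation matrix: %d residues, %d states, threshold %.2f A\n",
              nrow(x$A), x$n_states, x$threshold))
  cat(sprintf("  mu (off-diagonal mean) = %.3f; %d residues without significant motion\n",
              structural_correlation(x), sum(x$degenerate)))
  invisible(x)
}

#' Structural correlation parameter mu
#'
#' The average of the adjusted-mutual-information matrix.  By default the
#' diagonal (self-agreement, identically 1) is excluded so that an ensemble
#' without correlated motion averages to 0; `include_diagonal = TRUE`
#' restores the literal double sum over all `L^2` entries.  Slightly
#' negative averages (finite-sample anti-correlation) are clamped to 0 for
#' reporting; the raw value is kept in `attr(, "raw")`.
#'
#' @param matrix an `ms_cormat` from [correlation_matrix()] or a plain
#'   symmetric matrix.
#' @param include_diagonal include `i = j` terms (default FALSE).
#' @param exclude_empty drop rows/columns of residues whose clustering is
#'   degenerate (no significant motion) from the average; default FALSE
#'   (they count as zeros).
#' @return mu in `[0, 1]` with attribute `raw` (unclamped mean).
#' @export
structural_correlation <- function(matrix, include_diagonal = FALSE,
                                   exclude_empty = FALSE) {
  if (inherits(matrix, "ms_cormat")) {
    A <- matrix$A
    if (exclude_empty && any(matrix$degenerate)) {
      keep <- !matrix$degenerate
      if (!any(keep)) stopf("all residues are degenerate")
      A <- A[keep, keep, drop = FALSE]
    }
  } else {
    A <- as.matrix(matrix)
    if (exclude_empty) {
      keep <- rowSums(abs(A)) > 0
      if (!any(keep)) stopf("all rows are zero")
      A <- A[keep, keep, drop = FALSE]
    }
  }
  if (!length(A)) stopf("empty correlation matrix")
  vals <- if (include_diagonal) A else A[row(A) != col(A)]
  if (!length(vals)) vals <- diag(A)  # 1x1 matrix without diagonal
  raw <- mean(vals)
  structure(max(raw, 0), raw = raw)
}

#' Key residue and global state clustering
#'
#' The key residue is the residue whose clustering agrees best on average
#' with all others (maximal off-diagonal row mean of `A`; ties resolved to
#' the lowest residue index).  Its clustering vector is the optimal global
#' state assignment of the bundle's entities.
#'
#' @param matrix an `ms_cormat` from [correlation_matrix()].
#' @return list with `residue` (position index), `resid` (residue number),
#'   `row_mean`, and `clustering` (integer labels per entity).
#' @export
key_residue_and_clustering <- function(matrix) {
  stopifnot(inherits(matrix, "ms_cormat"))
  A <- matrix$A
  L <- nrow(A)
  rm_ <- (rowSums(A) - diag(A)) / max(L - 1L, 1L)
  if (all(rm_ == 0) && all(diag(A) == 0)) {
    warnf("all correlations are zero; returning the lowest-index residue with a degenerate clustering")
  }
  r <- which.max(rm_)  # which.max takes the first (lowest index) on ties
  list(residue = r, resid = matrix$residues[r], row_mean = rm_[r],
       clustering = matrix$clusterings[[r]])
}

#' Structural correlation analysis of a multi-state ensemble
#'
#' The top-level fitting function: clusters the entities of the bundle
#' residue by residue, assembles the adjusted-mutual-information matrix,
#' averages it to the structural correlation parameter mu, and determines
#' the key residue whose clustering defines the global state assignment.
#'
#' @inheritParams correlation_matrix
#' @param include_diagonal,exclude_empty passed to
#'   [structural_correlation()].
#' @return object of class `mscor`: list with `matrix` (`ms_cormat`), `mu`,
#'   `mu_raw`, `key_residue`, `global_clustering`, `n_states`, `call`.
#'   Methods: `print`, `summary`, `plot` (correlation heat map).
#' @examples
#' mdl <- make_two_state_model(length = 16, displacement = 4, seed = 1)
#' ens <- sample_ensemble(mdl, n_conformers = 15, seed = 1)
#' fit <- mscor(ens, n_states = 2)
#' fit$mu
#' @export
mscor <- function(ensemble, n_states = 2L, threshold = 0.5, seed = 0L,
                  atom_mode = "CA", restarts = 10L,
                  include_diagonal = FALSE, exclude_empty = FALSE) {
  cm <- correlation_matrix(ensemble, n_states = n_states,
                           threshold = threshold, seed = seed,
                           atom_mode = atom_mode, restarts = restarts)
  mu <- structural_correlation(cm, include_diagonal = include_diagonal,
                               exclude_empty = exclude_empty)
  key <- withCallingHandlers(
    key_residue_and_clustering(cm),
    warning = function(w) invokeRestart("muffleWarning"))
  structure(list(matrix = cm, mu = as.numeric(mu), mu_raw = attr(mu, "raw"),
                 key_residue = key$resid, key_position = key$residue,
                 global_clustering = key$clustering, n_states = cm$n_states,
                 call = match.call()),
            class = "mscor")
}

#' @export
print.mscor <- function(x, ...) {
  cat("Structural correlation analysis\n")
  cat(sprintf("  states assumed: %d, entities: %d, residues: %d\n",
              x$n_states, length(x$global_clustering), nrow(x$matrix$A)))
  cat(sprintf("  mu = %.3f (raw %.3f)\n", x$mu, x$mu_raw))
  cat(sprintf("  key residue: %d\n", x$key_residue))
  invisible(x)
}

#' @export
summary.mscor <- function(object, ...) {
  A <- object$matrix$A
  rm_ <- (rowSums(A) - diag(A)) / max(nrow(A) - 1L, 1L)
  sizes <- table(object$global_clustering)
  cat("Structural correlation analysis\n")
  cat(sprintf("  mu = %.3f (raw %.3f), %d x %d residue pairs\n",
              object$mu, object$mu_raw, nrow(A), nrow(A)))
  cat(sprintf("  key residue %d (row-mean AMI %.3f)\n",
              object$key_residue, max(rm_)))
  cat(sprintf("  global clustering sizes: %s\n",
              paste(sizes, collapse = " / ")))
  cat(sprintf("  residues without significant motion: %d of %d\n",
              sum(object$matrix$degenerate), nrow(A)))
  invisible(list(mu = object$mu, mu_raw = object$mu_raw,
                 row_means = rm_, key_residue = object$key_residue,
                 cluster_sizes = as.integer(sizes)))
}

#' @export
plot.mscor <- function(x, main = "Structural correlations (AMI)", ...) {
  A <- x$matrix$A
  L <- nrow(A)
  image(seq_len(L), seq_len(L), t(A[L:1, , drop = FALSE]),
        col = hcl.colors(64, "YlOrRd", rev = TRUE),
        xlab = "residue", ylab = "residue", axes = FALSE, main = main,
        zlim = c(min(A, 0), 1), ...)
  ticks <- pretty(seq_len(L))
  ticks <- ticks[ticks >= 1 & ticks <= L]
  axis(1, at = ticks, labels = x$matrix$residues[ticks])
  axis(2, at = L + 1 - ticks, labels = x$matrix$residues[ticks])
  invisible(x)
}

#' Export a correlation matrix as TSV
#' @param matrix an `ms_cormat` or `mscor` object.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_correlation_matrix <- function(matrix, path) {
  if (inherits(matrix, "mscor")) matrix <- matrix$matrix
  A <- matrix$A
  dimnames(A) <- list(matrix$residues, matrix$residues)
  utils::write.table(A, path, sep = "\t", quote = FALSE)
  invisible(path)
}
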