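#' Construct a distance-restraint set
#'
#' A restraint set couples a table of distance restraints with the weights
#' of the three restraint classes entering the target function: experimental
#' upper limits (`upper`), experimental lower limits (`lower`) and steric
#' lower limits (`steric`).
#'
#' @param restraints data.frame with columns `resid_a`, `resname_a`,
#'   `atom_a`, `resid_b`, `resname_b`, `atom_b`, `bound` (Angstrom),
#'   `type` (`"upper"`, `"lower"` or `"steric"`).
#' @param weights named numeric vector of non-negative weights for
#'   `upper`, `lower`, `steric`; default all 1.
#' @return object of class `ms_restraints`.
#' @export
restraint_set <- function(restraints,
                          weights = c(upper = 1, lower = 1, steric = 1)) {
  restraints <- as.data.frame(restraints, stringsAsFactors = FALSE)
  req <- c("resid_a", "resname_a", "atom_a", "resid_b", "resname_b",
           "atom_b", "bound", "type")
  if (!all(req %in% names(restraints)))
    stopf("restraints must have columns %s", paste(req, collapse = ", "))
  if (nrow(restraints)) {
    if (any(restraints$bound <= 0)) stopf("restraint bounds must be > 0")
    if (!all(restraints$type %in% c("upper", "lower", "steric")))
      stopf("restraint type must be upper, lower or steric")
    same <- restraints$resid_a == restraints$resid_b &
      restraints$atom_a == restraints$atom_b
    if (any(same))
      stopf("restraint %d connects an atom to itself", which(same)[1])
  }
  if (!all(c("upper", "lower", "steric") %in% names(weights)))
    stopf("weights must be named for upper, lower and steric")
  if (any(weights < 0)) stopf("weights must be >= 0")
  structure(list(restraints = restraints,
                 weights = weights[c("upper", "lower", "steric")]),
            class = "ms_restraints")
}

#' @export
print.ms_restraints <- function(x, ...) {
  cat(sprintf("Distance restraint set: %d restraints (%s)\n",
              nrow(x$restraints),
              paste(sprintf("%s: %d", c("upper", "lower", "steric"),
                            c(sum(x$restraints$type == "upper"),
                              sum(x$restraints$type == "lower"),
                              sum(x$restraints$type == "steric"))),
                    collapse = ", ")))
  invisible(x)
}

#' @rdname restraint_set
#' @param x an `ms_restraints` object.
#' @export
n_restraints <- function(x) nrow(x$restraints)

#' Keep a subset of restraints
#' @param x an `ms_restraints` object.
#' @param which integer indices into the restraint table.
#' @return an `ms_restraints` with the selected rows, weights unchanged.
#' @export
subset_restraints <- function(x, which) {
  restraint_set(x$restraints[which, , drop = FALSE], x$weights)
}

#' Read CYANA-style distance restraints (.upl / .lol)
#'
#' Parses whitespace-separated lines of the form
#' `resnum resname atomname resnum resname atomname distance`,
#' e.g. `11 TRP H 26 ASN HB2 3.85`.  Blank lines and `#` comments are
#' ignored.
#'
#' @param path restraint file path.
#' @param type restraint class assigned to every line: `"upper"` (for .upl
#'   files, default), `"lower"` or `"steric"` (.lol).
#' @param weights passed to [restraint_set()].
#' @return an `ms_restraints` object, restraints in file order.
#' @export
read_restraints <- function(path, type = c("upper", "lower", "steric"),
                            weights = c(upper = 1, lower = 1, steric = 1)) {
  type <- match.arg(type)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  keep <- which(nzchar(trimws(lines)))
  rows <- lapply(keep, function(i) {
    f <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    if (length(f) != 7L)
      stopf("line %d: expected 7 fields, found %d", i, length(f))
    d <- suppressWarnings(as.numeric(f[7]))
    ra <- suppressWarnings(as.integer(f[1]))
    rb <- suppressWarnings(as.integer(f[4]))
    if (is.na(ra) || is.na(rb))
      stopf("line %d: residue numbers must be integers", i)
    if (is.na(d) || d <= 0)
      stopf("line %d: distance must be a positive number", i)
    data.frame(resid_a = ra, resname_a = f[2], atom_a = f[3],
               resid_b = rb, resname_b = f[5], atom_b = f[6],
               bound = d, type = type, stringsAsFactors = FALSE)
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(resid_a = integer(), resname_a = character(),
               atom_a = character(), resid_b = integer(),
               resname_b = character(), atom_b = character(),
               bound = numeric(), type = character(),
               stringsAsFactors = FALSE)
  restraint_set(df, weights)
}

#' Write restraints in CYANA .upl/.lol format
#' @param x an `ms_restraints` object.
#' @param path output file; conventionally `.upl` for upper limits.
#' @param type which restraint class to write (default `"upper"`).
#' @return `path`, invisibly.
#' @export
write_restraints <- function(x, path, type = "upper") {
  df <- x$restraints[x$restraints$type == type, , drop = FALSE]
  lines <- sprintf("%4d %-4s %-5s %4d %-4s %-5s %8.2f",
                   df$resid_a, df$resname_a, df$atom_a,
                   df$resid_b, df$resname_b, df$atom_b, df$bound)
  writeLines(lines, path)
  invisible(path)
}

#' r^-6 ensemble-averaged distance
#'
#' The NOE-appropriate average over states,
#' `d* = (sum(w_i * d_i^-6))^(-1/6)` with weights `w_i` summing to 1
#' (equal weights `1/N` by default).  Because of the steep `r^-6` kernel the
#' average is dominated by the shortest state distance and always satisfies
#' `min(d) <= d* <= min(d) * N^(1/6)` at equal weights.
#'
#' @param d numeric vector of per-state distances, all `> 0`.
#' @param weights optional state populations (non-negative, re-normalized to
#'   sum to 1); default equal.
#' @return the averaged distance in the same units as `d`.
#' @export
r6_average <- function(d, weights = NULL) {
  if (!length(d)) stopf("at least one distance is required")
  if (any(!is.finite(d)) || any(d <= 0))
    stopf("all distances must be positive and finite")
  if (is.null(weights)) {
    m <- mean(d^-6)
  } else {
    if (length(weights) != length(d))
      stopf("weights and distances differ in length")
    if (any(weights < 0) || sum(weights) <= 0)
      stopf("weights must be non-negative with positive sum")
    w <- weights / sum(weights)
    m <- sum(w * d^-6)
  }
  m^(-1 / 6)
}

# Resolve one restraint side to atom row indices in the template.
# Exact (resid, atom name) match; with match_protons = TRUE an unresolved
# name falls back to the prefix group of protons in the residue (e.g. "HB"
# -> HB2, HB3), combined downstream by r^-6 summation.
resolve_atoms <- function(atoms, resid, name, match_protons = FALSE) {
  rows <- which(atoms$resid == resid & atoms$name == name)
  if (!length(rows) && match_protons) {
    in_res <- which(atoms$resid == resid)
    rows <- in_res[startsWith(atoms$name[in_res], name)]
  }
  if (!length(rows))
    stopf("restrained atom %s of residue %d not found in the ensemble",
          name, resid)
  rows
}

# Effective distance between two atom groups in one entity: single atoms give
# the plain Euclidean distance; proton groups are combined by r^-6 summation.
group_distance <- function(xyz, rows_a, rows_b) {
  if (length(rows_a) == 1L && length(rows_b) == 1L) {
    return(sqrt(sum((xyz[rows_a, ] - xyz[rows_b, ])^2)))
  }
  s <- 0
  for (a in rows_a) for (b in rows_b) {
    d <- sqrt(sum((xyz[a, ] - xyz[b, ])^2))
    s <- s + d^-6
  }
  s^(-1 / 6)
}

#' Distance-restraint target function of a multi-state bundle
#'
#' The weighted sum of squared violations over currently violated
#' restraints: for every conformer, the model distance of a restraint is the
#' r^-6 average over the conformer's `N` states ([r6_average()]); an upper
#' limit is violated when the averaged distance exceeds its bound, a lower or
#' steric limit when it falls below.  The reported value is the average over
#' conformers of the per-conformer sum `V_d`, the bundle-level convention
#' used when comparing calculations.
#'
#' @param ensemble an [ms_ensemble()] containing every restrained atom.
#' @param restraints an `ms_restraints` set ([restraint_set()]).
#' @param match_protons if TRUE, restraint atom names that do not resolve
#'   exactly are matched as proton-group prefixes and combined by r^-6
#'   summation; default FALSE (exact matching only).
#' @return object of class `ms_target`: list with `value` (mean `V_d` over
#'   conformers, Angstrom^2), `per_conformer` (numeric vector),
#'   `normalized` (`value` divided by the number of restraints), and
#'   `violations` (data.frame: conformer, restraint index, type, bound,
#'   model_distance, violation).
#' @export
target_function <- function(ensemble, restraints, match_protons = FALSE) {
  df <- restraints$restraints
  w <- restraints$weights
  M <- ensemble$n_conformers; N <- ensemble$n_states
  nR <- nrow(df)
  if (nR == 0L) {
    out <- list(value = 0, per_conformer = rep(0, M), normalized = 0,
                violations = data.frame(conformer = integer(),
                                        restraint = integer(),
                                        type = character(), bound = numeric(),
                                        model_distance = numeric(),
                                        violation = numeric()))
    return(structure(out, class = "ms_target"))
  }
  rows_a <- lapply(seq_len(nR), function(i)
    resolve_atoms(ensemble$atoms, df$resid_a[i], df$atom_a[i], match_protons))
  rows_b <- lapply(seq_len(nR), function(i)
    resolve_atoms(ensemble$atoms, df$resid_b[i], df$atom_b[i], match_protons))
  per_conf <- numeric(M)
  viol <- list()
  for (m in seq_len(M)) {
    v_sum <- 0
    for (i in seq_len(nR)) {
      ds <- vapply(seq_len(N), function(s)
        group_distance(ensemble$xyz[, , (m - 1L) * N + s],
                       rows_a[[i]], rows_b[[i]]), numeric(1))
      dstar <- r6_average(ds)
      b <- df$bound[i]
      excess <- if (df$type[i] == "upper") dstar - b else b - dstar
      if (excess > 0) {
        wc <- w[[df$type[i]]]
        v_sum <- v_sum + wc * excess^2
        viol[[length(viol) + 1L]] <- data.frame(
          conformer = m, restraint = i, type = df$type[i], bound = b,
          model_distance = dstar, violation = excess,
          stringsAsFactors = FALSE)
      }
    }
    per_conf[m] <- v_sum
  }
  violations <- if (length(viol)) do.call(rbind, viol) else
    data.frame(conformer = integer(), restraint = integer(),
               type = character(), bound = numeric(),
               model_distance = numeric(), violation = numeric())
  structure(list(value = mean(per_conf), per_conformer = per_conf,
                 normalized = mean(per_conf) / nR, violations = violations),
            class = "ms_target")
}

#' @export
print.ms_target <- function(x, ...) {
  cat(sprintf("Target function V_d = %.4f A^2 (normalized %.4f), %d violations in %d conformers\n",
              x$value, x$normalized, nrow(x$violations),
              length(x$per_conformer)))
  invisible(x)
}

#' Write a violations report as TSV
#' @param report an `ms_target` object from [target_function()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_violations <- function(report, path) {
  utils::write.table(report$violations, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
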