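# Per-protein curve families derived from a mode's displacement field:
# motion-magnitude curves (one value per residue) and rotation-angle curves
# (one value per inter-residue link).

#' Motion-magnitude curve of one protein in one mode
#'
#' For every residue of the protein subset, the mean Euclidean norm of its
#' atoms' displacements: per atom, magnitude = |displacement|; per residue,
#' the average over the residue's own atoms.
#'
#' @param displacements (number of atoms) x 3 matrix, e.g. from
#'   [mode_displacements()].
#' @param structure The `mol_structure` the displacements refer to.
#' @param protein A `residue_set` selecting the protein.
#' @param mode_number Optional mode label stored on the curve.
#' @return A `motion_curve` of kind `"magnitude"`: non-negative `values`
#'   (length = residue count), residue keys, protein label.
#' @export
magnitude_curve <- function(displacements, structure, protein, mode_number = NA) {
  stopifnot(inherits(structure, "mol_structure"), inherits(protein, "residue_set"))
  displacements <- as.matrix(displacements)
  if (nrow(displacements) != n_atoms(structure) || ncol(displacements) != 3L)
    stop("displacements must be an (n_atoms x 3) matrix")
  atom_mag <- sqrt(rowSums(displacements^2))
  idx <- set_atom_indices(structure, protein)
  if (any(lengths(idx) == 0L))
    stop("residue(s) without atoms in subset '", protein$label, "'")
  values <- vapply(idx, function(i) mean(atom_mag[i]), numeric(1))
  new_motion_curve(values, kind = "magnitude", protein_id = protein$label,
                   mode_number = mode_number, residue_keys = protein$keys)
}

new_motion_curve <- function(values, kind, protein_id = NA, mode_number = NA,
                             residue_keys = NULL, amplitude_used = NA) {
  structure(list(values = as.numeric(values), kind = kind,
                 protein_id = protein_id, mode_number = mode_number,
                 residue_keys = residue_keys, amplitude_used = amplitude_used),
            class = "motion_curve")
}

#' @export
print.motion_curve <- function(x, ...) {
  cat(sprintf("motion_curve (%s): protein %s, mode %s, %d values\n",
              x$kind, x$protein_id, x$mode_number, length(x$values)))
  invisible(x)
}

# numeric values of a curve or plain vector
curve_values <- function(x) {
  if (inherits(x, "motion_curve") || inherits(x, "condensed_curve")) x$values
  else as.numeric(x)
}

#' Displace a structure along a field
#'
#' Adds one displacement per atom to the equilibrium coordinates; all
#' identity metadata is unchanged.
#'
#' @inheritParams magnitude_curve
#' @param structure A `mol_structure`.
#' @return The deformed `mol_structure`.
#' @export
deform <- function(structure, displacements) {
  stopifnot(inherits(structure, "mol_structure"))
  displacements <- as.matrix(displacements)
  if (nrow(displacements) != n_atoms(structure) || ncol(displacements) != 3L)
    stop("displacements must be an (n_atoms x 3) matrix")
  out <- structure
  out$atoms$x <- out$atoms$x + displacements[, 1]
  out$atoms$y <- out$atoms$y + displacements[, 2]
  out$atoms$z <- out$atoms$z + displacements[, 3]
  out
}

# one representative point per residue of the set
residue_representatives <- function(structure, protein, representative) {
  idx <- set_atom_indices(structure, protein)
  a <- structure$atoms
  if (representative == "centroid") {
    t(vapply(idx, function(i) c(mean(a$x[i]), mean(a$y[i]), mean(a$z[i])),
             numeric(3)))
  } else {
    ca <- vapply(idx, function(i) {
      j <- i[a$name[i] == "CA"]
      if (!length(j)) NA_integer_ else j[1]
    }, integer(1))
    if (anyNA(ca))
      stop("residue(s) without a CA atom; use representative = \"centroid\"")
    cbind(a$x[ca], a$y[ca], a$z[ca])
  }
}

#' Rotation-angle curve of one protein between two conformations
#'
#' Each residue is reduced to a representative point (all-atom centroid by
#' default, or its CA atom); the link vector joins consecutive residues of
#' the subset in file order.  The curve holds, per link, the angle (radians,
#' clamped to \[0, pi\]) between the reference and deformed link vectors.
#' A zero-length link yields angle 0 with a warning.
#'
#' @param reference,deformed `mol_structure`s over the same residues, e.g.
#'   the equilibrium structure and its [deform()]ation along a mode.
#' @param protein A `residue_set` (at least 2 residues).
#' @param representative `"centroid"` or `"c-alpha"`.
#' @param mode_number Optional mode label stored on the curve.
#' @param amplitude_used Optional record of the deformation amplitude.
#' @return A `motion_curve` of kind `"angle"`, length = residue count - 1.
#' @export
rotation_angle_curve <- function(reference, deformed, protein,
                                 representative = c("centroid", "c-alpha"),
                                 mode_number = NA, amplitude_used = NA) {
  stopifnot(inherits(reference, "mol_structure"), inherits(deformed, "mol_structure"))
  representative <- match.arg(representative)
  if (length(protein$rows) < 2L) stop("need at least 2 residues for link vectors")
  if (n_atoms(reference) != n_atoms(deformed))
    stop("reference and deformed structures differ in atom count")
  p0 <- residue_representatives(reference, protein, representative)
  p1 <- residue_representatives(deformed, protein, representative)
  u <- diff(p0)   # links: residue k -> k+1
  v <- diff(p1)
  nu <- sqrt(rowSums(u^2))
  nv <- sqrt(rowSums(v^2))
  ang <- numeric(nrow(u))
  degen <- nu == 0 | nv == 0
  if (any(degen)) {
    warning("zero-length link vector(s); angle defined as 0", call. = FALSE)
    ang[degen] <- 0
  }
  ok <- !degen
  uo <- u[ok, , drop = FALSE]; vo <- v[ok, , drop = FALSE]
  dotp <- rowSums(uo * vo)
  crossn <- sqrt(rowSums(cbind(uo[, 2] * vo[, 3] - uo[, 3] * vo[, 2],
                               uo[, 3] * vo[, 1] - uo[, 1] * vo[, 3],
                               uo[, 1] * vo[, 2] - uo[, 2] * vo[, 1])^2))
  # atan2 form of arccos(u.v/|u||v|): identical angle, well-conditioned
  # near 0 and pi where the clamped-arccos form loses precision
  ang[ok] <- atan2(crossn, dotp)
  new_motion_curve(ang, kind = "angle", protein_id = protein$label,
                   mode_number = mode_number, residue_keys = protein$keys[-1],
                   amplitude_used = amplitude_used)
}

#' Write a family of curves to a tabular text file
#'
#' One row per residue (or link), one column per mode.
#'
#' @param curves Named list of `motion_curve`s (same protein, one per mode).
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_curves_tsv <- function(curves, path) {
  stopifnot(length(curves) >= 1L)
  vals <- lapply(curves, curve_values)
  L <- unique(lengths(vals))
  if (length(L) != 1L) stop("curves have unequal lengths")
  keys <- curves[[1]]$residue_keys %||% seq_len(L)
  out <- data.frame(index = seq_len(L), residue = keys)
  modes <- vapply(curves, function(cu) as.character(cu$mode_number %||% NA),
                  character(1))
  for (i in seq_along(vals)) out[[paste0("mode_", modes[i])]] <- vals[[i]]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
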